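# Single-leaf association scans: per-leaf-type trait against each SNP under
# LM (plain regression), Q (structure covariates) and QK (covariates +
# polygenic random effect with kinship covariance, EMMAX-style: variance
# components estimated once under the null and reused for every SNP).

#' Fit the null linear mixed model (no SNP)
#'
#' REML estimation of (sigma_g^2, sigma_e^2) for
#' y = X beta + eta + epsilon, eta ~ MVN(0, K sigma_g^2),
#' epsilon ~ MVN(0, I sigma_e^2), via the spectral decomposition of K and
#' 1-D optimization of the variance ratio.
#'
#' @param y trait vector (Box-Cox-normalized upstream as needed).
#' @param covariates optional matrix of structure covariates (no
#'   intercept; one is added).
#' @param K kinship: a \linkS4class{KinshipMatrix} (GRM) or PSD matrix.
#' @return list with \code{sigmaG2}, \code{sigmaE2}, \code{h2},
#'   \code{beta} (fixed effects), \code{logLik} (restricted),
#'   \code{boundary} (TRUE when the ratio hit the search bound, e.g. the
#'   unidentifiable K = I case).
#' @export
fitNullLmm <- function(y, covariates = NULL, K) {
  if (is(K, "KinshipMatrix")) {
    if (kinshipEstimator(K) != "grm")
      stop("the mixed model needs the GRM kinship (PSD covariance)")
    K <- kinshipValues(K)
  }
  n <- length(y)
  stopifnot(nrow(K) == n)
  if (sd(y) == 0) stop("y has zero variance")
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  p <- ncol(X)
  ev <- eigen(K, symmetric = TRUE)
  if (min(ev$values) < -1e-6 * max(abs(ev$values)))
    stop("K is not positive semi-definite")
  U <- ev$vectors; d <- pmax(ev$values, 0)
  yt <- crossprod(U, y); Xt <- crossprod(U, X)
  remlNegLL <- function(logLambda) {
    lam <- exp(logLambda)
    w <- lam * d + 1
    XtW <- Xt / w
    XX <- crossprod(Xt, XtW)
    b <- solve(XX, crossprod(XtW, yt))
    r <- yt - Xt %*% b
    rss <- sum(r^2 / w)
    s2 <- rss / (n - p)
    0.5 * ((n - p) * log(2 * pi * s2) + sum(log(w)) +
             determinant(XX)$modulus[1] -
             determinant(crossprod(X))$modulus[1] + (n - p))
  }
  grid <- seq(-12, 12, length.out = 49)
  vals <- vapply(grid, remlNegLL, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(remlNegLL, c(lo, hi))
  lam <- exp(opt$minimum)
  # flat profile (e.g. K = I) leaves the split unidentifiable
  boundary <- i %in% c(1, length(grid)) || diff(range(vals)) < 1e-8
  w <- lam * d + 1
  XtW <- Xt / w
  XX <- crossprod(Xt, XtW)
  b <- solve(XX, crossprod(XtW, yt))
  s2e <- sum((yt - Xt %*% b)^2 / w) / (n - p)
  list(sigmaG2 = lam * s2e, sigmaE2 = s2e,
       h2 = lam / (lam + 1), beta = drop(b),
       logLik = -opt$objective, boundary = boundary,
       eigenK = list(vectors = U, values = d), lambda = lam)
}

# whitening transform for the QK model: V^{-1/2} with V = sigmaG2 K + sigmaE2 I
.qkWhitener <- function(null) {
  w <- null$sigmaG2 * null$eigenK$values + null$sigmaE2
  t(null$eigenK$vectors / sqrt(w)[col(null$eigenK$vectors)]) # diag(1/sqrt(w)) %*% U'
}

#' Model specification for the single-leaf scan
#'
#' @param model "LM" (plain regression; the pipeline default), "Q"
#'   (structure covariates) or "QK" (covariates + kinship mixed model).
#' @param covariates matrix of structure covariates (required for Q and
#'   QK).
#' @param kinship a GRM \linkS4class{KinshipMatrix} (required for QK).
#' @return list of class \code{SingleLeafModelSpec}.
#' @export
singleLeafModel <- function(model = c("LM", "Q", "QK"), covariates = NULL,
                            kinship = NULL) {
  model <- match.arg(model)
  if (model %in% c("Q", "QK") && is.null(covariates))
    stop(model, " model requires structure covariates")
  if (model == "QK" && is.null(kinship))
    stop("QK model requires a kinship matrix")
  structure(list(model = model, covariates = covariates,
                 kinship = kinship), class = "SingleLeafModelSpec")
}

#' Per-SNP association scan for one single-leaf trait
#'
#' LM: ordinary least squares per SNP; Q: OLS with structure covariates
#' projected out; QK: GLS with covariance sigma_g^2 K + sigma_e^2 I fixed
#' at the null REML estimates (single whitening, then OLS -- the EMMAX
#' approximation). Wald t-tests throughout; missing genotypes are per-SNP
#' mean-imputed.
#'
#' @param y trait vector, ordered as the rows of \code{g}.
#' @param g a \linkS4class{GenotypeData} (or 0/1/2 matrix).
#' @param spec a \code{\link{singleLeafModel}}.
#' @return data.frame (one row per SNP): \code{chrom}, \code{pos},
#'   \code{effect}, \code{se}, \code{stat} (t), \code{p}; genomic
#'   inflation in \code{attr(, "lambdaGC")}, the model tag in
#'   \code{attr(, "model")}.
#' @export
assocScan <- function(y, g, spec = singleLeafModel("LM")) {
  G <- if (is(g, "GenotypeData")) genotypeCalls(g) else as.matrix(g)
  if (length(y) != nrow(G))
    stop("sample mismatch: y has ", length(y), " values but genotypes have ",
         nrow(G), " individuals")
  meta <- if (is(g, "GenotypeData")) snpMeta(g) else
    data.frame(chrom = "chr1", pos = seq_len(ncol(G)))
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  n <- length(y)
  X <- cbind(rep(1, n), spec$covariates)
  if (spec$model == "QK") {
    null <- fitNullLmm(y, spec$covariates, spec$kinship)
    Wh <- .qkWhitener(null)
    y <- drop(Wh %*% y); X <- Wh %*% X; G <- Wh %*% G
  }
  qrX <- qr(X)
  yr <- qr.resid(qrX, y)
  Gr <- qr.resid(qrX, G)
  sxx <- colSums(Gr^2)
  sxy <- colSums(Gr * yr)
  beta <- sxy / sxx
  df <- n - ncol(X) - 1
  rss <- pmax(sum(yr^2) - beta * sxy, 0)
  se <- sqrt(rss / df / sxx)
  tstat <- beta / se
  pval <- 2 * pt(-abs(tstat), df)
  mono <- sxx < 1e-10
  beta[mono] <- se[mono] <- tstat[mono] <- pval[mono] <- NA_real_
  out <- data.frame(chrom = meta$chrom, pos = meta$pos, effect = beta,
                    se = se, stat = tstat, p = pval)
  pOk <- pval[!is.na(pval)]
  attr(out, "lambdaGC") <- if (length(pOk) >= 10) lambdaGc(pOk) else NA_real_
  attr(out, "model") <- spec$model
  out
}

#' Genomic inflation factor
#'
#' Median of the chi-square(1) quantile-transformed p-values divided by the
#' null median 0.4549; ~1 indicates calibrated tests.
#'
#' @param pValues vector of p-values in (0, 1], length >= 10.
#' @return lambda_GC.
#' @export
lambdaGc <- function(pValues) {
  if (any(pValues <= 0 | pValues > 1)) stop("p-values must lie in (0, 1]")
  if (length(pValues) < 10) stop("need at least 10 p-values")
  median(qchisq(pValues, df = 1, lower.tail = FALSE)) / qchisq(0.5, 1)
}

#' Permutation threshold for a single-leaf scan
#'
#' Reshuffles the phenotype to break phenotype-genotype links, records the
#' genome-wide maximum squared association statistic per permutation, and
#' returns the empirical (1 - alpha) quantile (a family-wise critical
#' value on the chi-square scale: compare against stat^2).
#'
#' @param y,g,spec as in \code{\link{assocScan}}.
#' @param nPerm number of permutations (>= 100; default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed.
#' @return list with \code{threshold}, \code{maxStats}, \code{alpha},
#'   \code{nPerm}.
#' @export
permutationThreshold <- function(y, g, spec = singleLeafModel("LM"),
                                 nPerm = 1000L, alpha = 0.05, seed = 1L) {
  if (nPerm < 100) stop("nPerm must be >= 100 for a stable quantile")
  G <- if (is(g, "GenotypeData")) genotypeCalls(g) else as.matrix(g)
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  n <- length(y)
  X <- cbind(rep(1, n), spec$covariates)
  if (spec$model == "QK") {
    null <- fitNullLmm(y, spec$covariates, spec$kinship)
    Wh <- .qkWhitener(null)
    yW <- drop(Wh %*% y); X <- Wh %*% X; G <- Wh %*% G
  }
  qrX <- qr(X)
  Gr <- qr.resid(qrX, G)
  sxx <- colSums(Gr^2)
  ok <- sxx > 1e-10
  df <- n - ncol(X) - 1
  set.seed(seed)
  maxStats <- vapply(seq_len(nPerm), function(b) {
    yp <- y[sample.int(n)]
    if (spec$model == "QK") yp <- drop(Wh %*% yp)
    yr <- qr.resid(qrX, yp)
    sxy <- colSums(Gr * yr)
    beta <- sxy / sxx
    rss <- pmax(sum(yr^2) - beta * sxy, 1e-300)
    t2 <- beta^2 * sxx * df / rss
    max(t2[ok])
  }, numeric(1))
  list(threshold = unname(quantile(maxStats, 1 - alpha)),
       maxStats = maxStats, alpha = alpha, nPerm = nPerm)
}
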