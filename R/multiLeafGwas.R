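# Multi-leaf association scan: per-SNP genotype-group mean 4-vectors with a
# shared SAD(1) covariance, likelihood-ratio tested against a common-mean null.
#
# The SAD(1) residual recursion e_t = phi*e_{t-1} + eps_t (e_0 = 0) factors the
# covariance as Sigma = nu2 * L L' with L unit lower-triangular (L[t,s] =
# phi^(t-s)), so det(Sigma) = nu2^T and the profile log-likelihood in phi is a
# quadratic: given a pooled within-group cross-product matrix W (MLE scale),
#   tr(Sigma^{-1} W) = (c0 - 2*phi*c1 + phi^2*c2) / nu2
# with c0 = sum_t W[t,t], c1 = sum_{t>=2} W[t,t-1], c2 = sum_{t>=2} W[t-1,t-1].
# The MLE is therefore exact: phi = c1/c2, nu2 = (c0 - 2*phi*c1 + phi^2*c2)/T,
# and logL = -nT/2 * (log(2*pi) + 1 + log(nu2)). No numerical optimization is
# needed, which is what makes genome-wide permutation thresholds affordable.

#' SAD(1) covariance matrix over T serial positions
#'
#' Builds the covariance implied by the first-order antedependence recursion
#' \eqn{e_t = \phi e_{t-1} + \epsilon_t}, \eqn{\epsilon_t \sim N(0,\nu^2)},
#' \eqn{e_0 = 0}: \eqn{\Sigma = \nu^2 L L'} with L unit lower-triangular,
#' \eqn{L_{ts} = \phi^{t-s}} for \eqn{t \ge s}. The matrix is positive
#' definite for every real phi and nu2 > 0.
#'
#' @param params a \linkS4class{Sad1Params}.
#' @param T number of serial positions (canopy leaf positions; default 4).
#' @return T x T covariance matrix.
#' @examples
#' sad1Covariance(Sad1Params(phi = 0.5, nu2 = 1), T = 2)
#' @export
sad1Covariance <- function(params, T = 4L) {
  stopifnot(is(params, "Sad1Params"), T >= 1)
  L <- .sadL(params@phi, T)
  params@nu2 * tcrossprod(L)
}

.sadL <- function(phi, T) {
  L <- diag(1, T)
  if (T > 1)
    for (t in 2:T) for (s in 1:(t - 1)) L[t, s] <- phi^(t - s)
  L
}

# Exact SAD(1) profile MLE from band sums of a cross-product matrix.
# cp scale: sums of squares/products (not yet divided by n).
.sadMLEFromBands <- function(c0, c1, c2, n, T) {
  phi <- ifelse(c2 > 0, c1 / c2, 0)
  q <- c0 - 2 * phi * c1 + phi^2 * c2
  nu2 <- q / (n * T)
  logL <- -n * T / 2 * (log(2 * pi) + 1 + log(nu2))
  list(phi = phi, nu2 = nu2, logLik = logL)
}

.bandSums <- function(CP) {
  T <- nrow(CP)
  c0 <- sum(diag(CP))
  c1 <- sum(CP[cbind(2:T, 1:(T - 1))])
  c2 <- sum(diag(CP)[1:(T - 1)])
  c(c0 = c0, c1 = c1, c2 = c2)
}

#' Fit the reduced (common-mean) multi-leaf model
#'
#' Maximum likelihood under H0: all individuals share one mean 4-vector and a
#' SAD(1) covariance. The mean MLE is the sample mean; (phi, nu2) maximize the
#' profile likelihood exactly (closed form via the innovation factorization).
#'
#' @param pheno numeric matrix, individuals x T (T = 4 canopy positions),
#'   complete cases only.
#' @return list with \code{mean} (length-T), \code{params}
#'   (\linkS4class{Sad1Params}), \code{logLik}, \code{n}.
#' @examples
#' set.seed(1)
#' y <- MASS::mvrnorm(200, rep(0, 4), sad1Covariance(Sad1Params(0.6, 2)))
#' fitSadNull(y)$params
#' @export
fitSadNull <- function(pheno) {
  pheno <- as.matrix(pheno)
  n <- nrow(pheno); T <- ncol(pheno)
  if (n < 5) stop("need at least 5 individuals")
  if (any(is.na(pheno))) stop("pheno must be complete (no NA)")
  mu <- colMeans(pheno)
  R <- sweep(pheno, 2, mu)
  CP <- crossprod(R)
  if (sum(diag(CP)) <= 0)
    stop("degenerate phenotypes: zero residual variance")
  b <- .bandSums(CP)
  f <- .sadMLEFromBands(b["c0"], b["c1"], b["c2"], n, T)
  if (f$nu2 <= 0) stop("degenerate phenotypes: zero innovation variance")
  list(mean = mu, params = Sad1Params(unname(f$phi), unname(f$nu2)),
       logLik = unname(f$logLik), n = n)
}

#' Fit the full (genotype-group means) multi-leaf model at one SNP
#'
#' Individuals are grouped by genotype (0/1/2 copies of the alternate
#' allele); each group gets its own mean 4-vector (MLE = the group sample
#' mean, exact under a shared covariance) and all groups share one SAD(1)
#' covariance fitted by exact profile ML on the pooled within-group
#' residuals. Groups smaller than \code{minGroup} (and individuals with a
#' missing genotype) are excluded from the fit; the null likelihood is
#' re-evaluated on the same retained subset so the likelihood-ratio
#' statistic is never negative.
#'
#' @param pheno individuals x 4 phenotype matrix.
#' @param genotype integer vector (0/1/2/NA) along individuals.
#' @param minGroup minimum genotype-group size (default 5).
#' @return list with \code{groupMeans} (J x 4), \code{groups} (genotype
#'   codes), \code{nj}, \code{params}, \code{logLik} (full model),
#'   \code{logLikNull} (common mean, same subset), \code{lrt}, \code{df}
#'   (4 * (J - 1)), \code{n} (analyzed), \code{dropped} (individuals
#'   excluded).
#' @export
fitSadFull <- function(pheno, genotype, minGroup = 5L) {
  pheno <- as.matrix(pheno)
  T <- ncol(pheno)
  stopifnot(length(genotype) == nrow(pheno))
  keepG <- !is.na(genotype)
  tab <- table(genotype[keepG])
  okGroups <- as.integer(names(tab)[tab >= minGroup])
  keep <- keepG & genotype %in% okGroups
  n <- sum(keep)
  J <- length(okGroups)
  if (J < 2)
    stop("fewer than 2 genotype groups of size >= minGroup; SNP skipped")
  Y <- pheno[keep, , drop = FALSE]
  g <- genotype[keep]
  gm <- rowsum(Y, g) / as.vector(table(g))
  R <- Y - gm[match(g, sort(unique(g))), , drop = FALSE]
  bF <- .bandSums(crossprod(R))
  fF <- .sadMLEFromBands(bF["c0"], bF["c1"], bF["c2"], n, T)
  R0 <- sweep(Y, 2, colMeans(Y))
  b0 <- .bandSums(crossprod(R0))
  f0 <- .sadMLEFromBands(b0["c0"], b0["c1"], b0["c2"], n, T)
  list(groupMeans = gm, groups = sort(unique(g)),
       nj = as.vector(table(g)),
       params = Sad1Params(unname(fF$phi), unname(fF$nu2)),
       logLik = unname(fF$logLik), logLikNull = unname(f0$logLik),
       lrt = unname(max(0, 2 * (fF$logLik - f0$logLik))),
       df = 4L * (J - 1L), n = n, dropped = nrow(pheno) - n)
}

# ---- vectorized scan machinery --------------------------------------------

# Precompute genotype-class indicator cross-product operators for one
# genotype matrix so that repeated scans (permutations) only cost three
# (n x m)' (n x 11) products each.
.scanPrep <- function(G, minGroup = 5L) {
  G <- as.matrix(G)
  n <- nrow(G); m <- ncol(G)
  Ig <- lapply(0:2, function(v) {
    M <- (G == v)
    M[is.na(M)] <- FALSE
    storage.mode(M) <- "double"
    M
  })
  ng <- vapply(Ig, colSums, numeric(m))          # m x 3
  retain <- ng >= minGroup                        # m x 3
  nEff <- rowSums(ng * retain)
  J <- rowSums(retain)
  list(Ig = Ig, ng = ng, retain = retain, nEff = nEff, J = J,
       n = n, m = m, minGroup = minGroup)
}

# Per-SNP LRT (and SAD parameters, PVE) for phenotype matrix Y given a prep.
.scanStats <- function(prep, Y) {
  T <- ncol(Y)
  H <- cbind(Y, Y^2, Y[, -1, drop = FALSE] * Y[, -T, drop = FALSE])
  m <- prep$m
  Sg <- Qg <- vector("list", 3)
  Pg <- vector("list", 3)
  for (k in 1:3) {
    M <- crossprod(prep$Ig[[k]], H)              # m x (2T + T-1)
    Sg[[k]] <- M[, 1:T, drop = FALSE]
    Qg[[k]] <- M[, (T + 1):(2 * T), drop = FALSE]
    Pg[[k]] <- M[, (2 * T + 1):(3 * T - 1), drop = FALSE]
  }
  r <- prep$retain
  nEff <- prep$nEff
  Stot <- Qtot <- matrix(0, m, T)
  Ptot <- matrix(0, m, T - 1)
  SSb <- matrix(0, m, T)                          # sum_g S_g^2 / n_g
  SPb <- matrix(0, m, T - 1)                      # sum_g S_g[t+1] S_g[t] / n_g
  for (k in 1:3) {
    w <- r[, k] / pmax(prep$ng[, k], 1)
    rk <- r[, k]
    Stot <- Stot + rk * Sg[[k]]
    Qtot <- Qtot + rk * Qg[[k]]
    Ptot <- Ptot + rk * Pg[[k]]
    SSb <- SSb + w * Sg[[k]]^2
    SPb <- SPb + w * Sg[[k]][, -1, drop = FALSE] * Sg[[k]][, -T, drop = FALSE]
  }
  # within-group (full model) cross-product band sums
  ssW <- Qtot - SSb
  spW <- Ptot - SPb
  # total (null model, same subset) band sums
  ss0 <- Qtot - Stot^2 / nEff
  sp0 <- Ptot - Stot[, -1, drop = FALSE] * Stot[, -T, drop = FALSE] / nEff
  mleBand <- function(ss, sp) {
    c0 <- rowSums(ss)
    c1 <- rowSums(sp)
    c2 <- rowSums(ss[, -T, drop = FALSE])
    phi <- ifelse(c2 > 0, c1 / c2, 0)
    q <- pmax(c0 - 2 * phi * c1 + phi^2 * c2, 0)
    list(phi = phi, nu2 = q / (nEff * T))
  }
  full <- mleBand(ssW, spW)
  null <- mleBand(ss0, sp0)
  lrt <- nEff * T * (log(null$nu2) - log(full$nu2))
  lrt <- pmax(lrt, 0)
  bad <- prep$J < 2 | full$nu2 <= 0 | null$nu2 <= 0
  lrt[bad] <- NA_real_
  pveT <- 100 * (SSb - Stot^2 / nEff) / ss0       # m x T, percent
  pveT[!is.finite(pveT)] <- NA_real_
  list(lrt = lrt, phi = full$phi, nu2 = full$nu2,
       phiNull = null$phi, nu2Null = null$nu2,
       pve = pveT, J = prep$J, n = nEff)
}

#' Multi-leaf likelihood-ratio scan over all SNPs
#'
#' For each SNP, compares the full model (one SAD(1)-covariance MVN per
#' genotype group with its own mean 4-vector) against the reduced model
#' (common mean), LRT = 2 (logL_full - logL_null). Group means are exact
#' MLEs; (phi, nu2) are exact profile MLEs. Monomorphic SNPs (fewer than 2
#' genotype groups of size >= \code{minGroup}) get \code{NA}.
#'
#' @param pheno individuals x 4 matrix of multi-leaf phenotypes (one trait
#'   observed on the four canopy leaf types, bottom to top), complete cases.
#' @param geno a \linkS4class{GenotypeData} (or plain 0/1/2 matrix).
#' @param minGroup minimum genotype-group size (default 5).
#' @return data.frame with one row per SNP: \code{chrom}, \code{pos},
#'   \code{J}, \code{n}, \code{lrt}, \code{df}, \code{phi}, \code{nu2},
#'   \code{pve1..pve4} (percent, per canopy position) and \code{pve}
#'   (their maximum).
#' @examples
#' cfg <- simConfig(n_individuals = 100, n_snps = 50, n_qtl = 1, seed = 2)
#' g <- simulateGenotypes(cfg)
#' ph <- simulatePhenotypes(g, cfg)
#' scan <- lrtScan(ph$phenotypes, g)
#' head(scan)
#' @export
lrtScan <- function(pheno, geno, minGroup = 5L) {
  G <- if (is(geno, "GenotypeData")) genotypeCalls(geno) else as.matrix(geno)
  pheno <- as.matrix(pheno)
  stopifnot(nrow(pheno) == nrow(G), ncol(pheno) == 4)
  if (any(is.na(pheno))) stop("pheno must be complete; drop incomplete trees")
  prep <- .scanPrep(G, minGroup)
  st <- .scanStats(prep, pheno)
  meta <- if (is(geno, "GenotypeData")) snpMeta(geno) else
    data.frame(chrom = "chr1", pos = seq_len(ncol(G)))
  out <- data.frame(chrom = meta$chrom, pos = meta$pos,
                    J = st$J, n = st$n, lrt = st$lrt,
                    df = 4L * (pmax(st$J, 1L) - 1L),
                    phi = st$phi, nu2 = st$nu2)
  colnames(st$pve) <- paste0("pve", 1:4)
  out <- cbind(out, st$pve)
  out$pve <- suppressWarnings(apply(st$pve, 1, max))
  out$pve[!is.finite(out$pve)] <- NA_real_
  out$lrt[st$J < 2] <- NA_real_
  out
}

#' Permutation threshold for the multi-leaf scan
#'
#' Permutes whole phenotype 4-vectors across individuals (keeping each
#' tree's four leaf values together, so the SAD(1) structure is preserved
#' under the null), records the genome-wide maximum LRT per permutation,
#' and returns the empirical (1 - alpha) quantile.
#'
#' @param pheno,geno,minGroup as in \code{\link{lrtScan}}.
#' @param nPerm number of permutations (>= 100; default 1000).
#' @param alpha family-wise significance level (default 0.05).
#' @param seed RNG seed for reproducible permutations.
#' @return list with \code{threshold}, \code{maxStats} (length nPerm),
#'   \code{alpha}, \code{nPerm}.
#' @export
permutationThresholdMulti <- function(pheno, geno, nPerm = 1000L,
                                      alpha = 0.05, seed = 1L,
                                      minGroup = 5L) {
  if (nPerm < 100) stop("nPerm must be >= 100 for a stable quantile")
  G <- if (is(geno, "GenotypeData")) genotypeCalls(geno) else as.matrix(geno)
  pheno <- as.matrix(pheno)
  prep <- .scanPrep(G, minGroup)
  set.seed(seed)
  n <- nrow(pheno)
  maxStats <- vapply(seq_len(nPerm), function(b) {
    st <- .scanStats(prep, pheno[sample.int(n), , drop = FALSE])
    max(st$lrt, na.rm = TRUE)
  }, numeric(1))
  list(threshold = unname(quantile(maxStats, 1 - alpha)),
       maxStats = maxStats, alpha = alpha, nPerm = nPerm)
}

#' Phenotypic variance explained by a fitted SNP
#'
#' Per canopy position t, the between-genotype-group variance of the fitted
#' means (weighted by group sizes) divided by the total phenotypic variance
#' of position t on the analyzed subset, in percent; the summary value is
#' the maximum over the four positions.
#'
#' @param fit a single-SNP fit from \code{\link{fitSadFull}}.
#' @param pheno the phenotype matrix the fit was made from.
#' @param genotype the SNP genotype vector the fit was made from.
#' @return list with \code{perPosition} (percent, length 4) and \code{max}.
#' @export
pve <- function(fit, pheno, genotype) {
  pheno <- as.matrix(pheno)
  keep <- !is.na(genotype) & genotype %in% fit$groups
  Y <- pheno[keep, , drop = FALSE]
  g <- genotype[keep]
  tot <- colMeans(sweep(Y, 2, colMeans(Y))^2)
  if (any(tot <= 0)) stop("zero total variance at some position")
  gm <- fit$groupMeans
  w <- fit$nj / sum(fit$nj)
  grand <- colSums(w * gm)
  btw <- colSums(w * sweep(gm, 2, grand)^2)
  per <- 100 * btw / tot
  list(perPosition = per, max = max(per))
}
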