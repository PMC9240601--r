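# Synthetic-data generator: biallelic genotypes (optional two-subpopulation
# structure), four-leaf-type phenotypes with planted QTLs, polygenic term and
# SAD(1) residuals, and parametric leaf outlines -- all with recorded ground
# truth so every downstream stage is testable without external data.

#' Simulation configuration
#'
#' Collects every generator parameter with validation. Defaults match the
#' package's reference null conditions: 300 trees, 1,000 independent SNPs
#' with allele frequencies uniform on [0.05, 0.5], no QTLs, no polygenic
#' term, SAD(1) residuals with phi = 0.5 and nu2 = 1, no subpopulation
#' structure, no missingness.
#'
#' @param n_individuals number of trees.
#' @param n_snps number of SNPs.
#' @param maf_range length-2 allele-frequency range, within (0, 0.5].
#' @param n_qtl number of planted QTLs (must be <= n_snps).
#' @param qtl_effects n_qtl x 4 matrix of additive effects per canopy
#'   position (trait units per alternate-allele copy); required when
#'   n_qtl > 0.
#' @param sad_phi SAD(1) antedependence coefficient.
#' @param sad_nu2 SAD(1) innovation variance (> 0).
#' @param polygenic_h2 fraction of residual variance assigned to a shared
#'   polygenic term, in [0, 1).
#' @param fst differentiation between the two optional subpopulations, in
#'   [0, 1); 0 disables structure.
#' @param missing_rate uniform genotype missingness rate (default 0).
#' @param baseline length-4 mean vector for the four canopy positions
#'   bottom to top (defaults on the leaf-index scale of the four classes:
#'   5, 2.8, 1.4, 0.8).
#' @param n_chrom number of chromosomes SNPs are spread over (default 5).
#' @param chrom_length chromosome length in bp (default 1e7).
#' @param seed RNG seed.
#' @return a validated list of class \code{SimConfig}.
#' @export
simConfig <- function(n_individuals = 300L, n_snps = 1000L,
                      maf_range = c(0.05, 0.5), n_qtl = 0L,
                      qtl_effects = NULL, sad_phi = 0.5, sad_nu2 = 1,
                      polygenic_h2 = 0, fst = 0, missing_rate = 0,
                      baseline = c(5, 2.8, 1.4, 0.8),
                      n_chrom = 5L, chrom_length = 1e7, seed = 1L) {
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5)
      || maf_range[1] > maf_range[2])
    stop("configuration error: maf_range must be within (0, 0.5]")
  if (sad_nu2 <= 0) stop("configuration error: sad_nu2 must be > 0")
  if (polygenic_h2 < 0 || polygenic_h2 >= 1)
    stop("configuration error: polygenic_h2 must be in [0, 1)")
  if (fst < 0 || fst >= 1) stop("configuration error: fst must be in [0, 1)")
  if (n_qtl > n_snps) stop("configuration error: n_qtl must be <= n_snps")
  if (n_qtl > 0) {
    if (is.null(qtl_effects)) stop("qtl_effects required when n_qtl > 0")
    qtl_effects <- matrix(qtl_effects, nrow = n_qtl)
    if (ncol(qtl_effects) != 4)
      stop("qtl_effects must have 4 columns (one per leaf position)")
  }
  if (length(baseline) != 4) stop("baseline must have length 4")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_snps = as.integer(n_snps), maf_range = maf_range,
                 n_qtl = as.integer(n_qtl), qtl_effects = qtl_effects,
                 sad_phi = sad_phi, sad_nu2 = sad_nu2,
                 polygenic_h2 = polygenic_h2, fst = fst,
                 missing_rate = missing_rate, baseline = baseline,
                 n_chrom = as.integer(n_chrom),
                 chrom_length = chrom_length, seed = as.integer(seed)),
            class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig:", x$n_individuals, "individuals,", x$n_snps, "SNPs,",
      x$n_qtl, "QTL(s); SAD(1) phi =", x$sad_phi, "nu2 =", x$sad_nu2,
      "; h2 =", x$polygenic_h2, "; Fst =", x$fst, "; seed =", x$seed, "\n")
  invisible(x)
}

#' Simulate biallelic SNP genotypes
#'
#' Per-SNP alternate-allele frequencies are drawn uniformly from
#' \code{maf_range}. With \code{fst > 0}, two equal subpopulations receive
#' Balding-Nichols-diverged frequencies
#' \eqn{p_k \sim Beta(p(1-F)/F, (1-p)(1-F)/F)} and genotypes are binomial
#' within subpopulation. Missing calls (if any) are planted uniformly at
#' random. Deterministic under the configured seed.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return a \linkS4class{GenotypeData}; the subpopulation labels (when
#'   fst > 0) are recorded in \code{attr(, "subpop")}, and the drawn allele
#'   frequencies in \code{attr(, "trueFreq")}.
#' @export
simulateGenotypes <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  n <- cfg$n_individuals; m <- cfg$n_snps
  p <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  subpop <- rep(1L, n)
  if (cfg$fst > 0) {
    subpop <- rep(1:2, length.out = n)
    F <- cfg$fst
    p1 <- rbeta(m, p * (1 - F) / F, (1 - p) * (1 - F) / F)
    p2 <- rbeta(m, p * (1 - F) / F, (1 - p) * (1 - F) / F)
    P <- rbind(p1, p2)[subpop, , drop = FALSE]     # n x m
    calls <- matrix(rbinom(n * m, 2, P), n, m)
  } else {
    calls <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  }
  if (cfg$missing_rate > 0)
    calls[runif(n * m) < cfg$missing_rate] <- NA_real_
  chrom <- sort(rep_len(seq_len(cfg$n_chrom), m))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix)
    sort(sample.int(cfg$chrom_length, length(ix)))), use.names = FALSE)
  meta <- data.frame(chrom = paste0("chr", chrom), pos = pos,
                     ref = "A", alt = "T",
                     mq = 60, depth = 50)
  g <- GenotypeData(calls, meta)
  attr(g, "subpop") <- subpop
  attr(g, "trueFreq") <- p
  g
}

#' Simulate four-leaf-type phenotypes with known ground truth
#'
#' Each tree i receives a 4-vector (one value per canopy leaf position,
#' bottom to top): baseline + sum over QTLs of genotype * effect + a
#' polygenic value shared across the four positions + SAD(1) residuals.
#' The polygenic term is MVN(0, sigma_g^2 * K) with K the realized
#' relationship matrix of the simulated genotypes and sigma_g^2 chosen so
#' that polygenic_h2 = sigma_g^2 / (sigma_g^2 + mean diag Sigma_SAD).
#'
#' @param geno a \linkS4class{GenotypeData} from
#'   \code{\link{simulateGenotypes}} (or real data).
#' @param cfg the \code{\link{simConfig}} used.
#' @return list with \code{phenotypes} (n x 4 matrix) and \code{truth}
#'   (QTL indices and effects, SAD parameters, per-QTL true genotype-group
#'   mean 4-vectors).
#' @export
simulatePhenotypes <- function(geno, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  G <- genotypeCalls(geno)
  n <- nrow(G)
  set.seed(cfg$seed + 1L)
  qtlIdx <- integer(0)
  Y <- matrix(rep(cfg$baseline, each = n), n, 4)
  if (cfg$n_qtl > 0) {
    qtlIdx <- sort(sample.int(ncol(G), cfg$n_qtl))
    B <- cfg$qtl_effects
    if (nrow(B) != cfg$n_qtl)
      stop("dimension mismatch: qtl_effects rows must equal n_qtl")
    X <- G[, qtlIdx, drop = FALSE]
    X[is.na(X)] <- 0
    Y <- Y + X %*% B
  }
  Sigma <- sad1Covariance(Sad1Params(cfg$sad_phi, cfg$sad_nu2), 4L)
  if (cfg$polygenic_h2 > 0) {
    K <- kinshipValues(kinship(geno, method = "grm"))
    sigmaG2 <- cfg$polygenic_h2 / (1 - cfg$polygenic_h2) * mean(diag(Sigma))
    ev <- eigen(K, symmetric = TRUE)
    rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
    gEff <- sqrt(sigmaG2) * as.vector(rt %*% rnorm(n))
    Y <- Y + gEff
  }
  Lm <- .sadL(cfg$sad_phi, 4L)
  eps <- matrix(rnorm(n * 4, sd = sqrt(cfg$sad_nu2)), n, 4)
  Y <- Y + eps %*% t(Lm)
  groupMeans <- if (cfg$n_qtl > 0)
    lapply(seq_len(cfg$n_qtl), function(q)
      t(vapply(0:2, function(x) cfg$baseline + x * cfg$qtl_effects[q, ],
               numeric(4))))
  else list()
  colnames(Y) <- c("linear", "lanceolate", "ovoid", "broad_ovate")
  list(phenotypes = Y,
       truth = list(qtl_indices = qtlIdx, qtl_effects = cfg$qtl_effects,
                    phi = cfg$sad_phi, nu2 = cfg$sad_nu2,
                    group_means = groupMeans))
}

#' Simulate leaf outlines with target leaf indices
#'
#' Generates a closed parametric leaf curve per row of \code{traits}: an
#' ellipse-based polar curve with a taper that narrows the tip, with the
#' width axis rescaled so the realized length/width ratio equals the target
#' LI exactly. The tip taper makes the base->tip axis identifiable even for
#' broad-ovate leaves (LI < 1).
#'
#' @param traits data.frame with columns \code{tree_id}, \code{leaf_type}
#'   and \code{LI} (target leaf index, > 0); an optional \code{LL} column
#'   sets the leaf length in units (default 100).
#' @param cfg optional \code{\link{simConfig}} (unused fields ignored).
#' @param taper tip-narrowing parameter in [0, 1) (default 0.35; 0 with
#'   LI = 1 gives a circle).
#' @param nPoints vertices per outline (default 300).
#' @return list of \linkS4class{LeafOutline} objects.
#' @examples
#' out <- simulateOutlines(data.frame(tree_id = "t1", leaf_type = "linear",
#'                                    LI = 4))[[1]]
#' unname(descriptiveTraits(out)["LI"])
#' @export
simulateOutlines <- function(traits, cfg = NULL, taper = 0.35,
                             nPoints = 300L) {
  stopifnot(all(c("tree_id", "leaf_type", "LI") %in% colnames(traits)))
  if (any(!is.finite(traits$LI) | traits$LI <= 0))
    stop("LI must be > 0 for every row")
  LLs <- if ("LL" %in% colnames(traits)) traits$LL else rep(100, nrow(traits))
  lapply(seq_len(nrow(traits)), function(i) {
    .leafCurve(traits$LI[i], LL = LLs[i], taper = taper,
               nPoints = nPoints, treeId = traits$tree_id[i],
               leafType = traits$leaf_type[i])
  })
}

# Parametric leaf archetype: x(t) = cos t (tip at +x), half-width profile
# w(t) = sin t * (1 - taper * cos t); the y scale is solved so LL/LW hits
# the target exactly.
.leafCurve <- function(LI, LL = 100, taper = 0.35, nPoints = 300L,
                       treeId = NA_character_, leafType = "unassigned") {
  t <- seq(0, 2 * pi, length.out = nPoints + 1)[-(nPoints + 1)]
  xs <- cos(t)
  ys <- sin(t) * (1 - taper * cos(t))
  xs <- xs * LL / diff(range(xs))
  # scale the width so the realized vertex extents hit the target exactly
  ys <- ys * (LL / LI) / diff(range(ys))
  LeafOutline(cbind(x = xs, y = ys), treeId = treeId, leafType = leafType)
}
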