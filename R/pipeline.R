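# End-to-end orchestration: synthetic or file-based inputs through
# morphometrics, filtering, structure, both association scans, permutation
# thresholds and candidate regions, with a reproducible manifest.

#' Pipeline configuration
#'
#' All defaults follow the package's reference settings: 1,000
#' permutations at alpha = 0.05, +/-100 kb candidate windows, 50 kb
#' cluster gap, 96% cumulative shape-PC variance, L = 100 semi-landmarks,
#' 25 EF harmonics, LM as the default single-leaf model.
#'
#' @param vcf path to a VCF (NULL when \code{simulate} is given).
#' @param traits path to a trait CSV with columns \code{tree_id},
#'   \code{leaf_type}, trait columns (NULL when simulating).
#' @param gff optional GFF3 gene models for candidate regions.
#' @param outDir output directory (created); NULL disables file output.
#' @param simulate optional \code{\link{simConfig}} generating genotypes
#'   and phenotypes in place of files.
#' @param L,nHarmonics,pcaCumThreshold morphometrics settings.
#' @param model single-leaf model ("LM", "Q" or "QK").
#' @param nPerm,alpha permutation settings.
#' @param window,clusterGap candidate-region settings (bp).
#' @param seed master seed; every random stage derives from it.
#' @return list of class \code{RunConfig}.
#' @export
runConfig <- function(vcf = NULL, traits = NULL, gff = NULL, outDir = NULL,
                      simulate = NULL, L = 100L, nHarmonics = 25L,
                      pcaCumThreshold = 0.96, model = "LM",
                      nPerm = 1000L, alpha = 0.05, window = 1e5,
                      clusterGap = 5e4, seed = 1L) {
  if (is.null(simulate)) {
    if (is.null(vcf) || !file.exists(vcf))
      stop("config error: vcf path missing or nonexistent")
    if (is.null(traits) || !file.exists(traits))
      stop("config error: traits path missing or nonexistent")
  }
  if (!is.null(gff) && !file.exists(gff))
    stop("config error: gff path nonexistent")
  stopifnot(alpha > 0, alpha < 1, nPerm >= 100, pcaCumThreshold > 0,
            pcaCumThreshold <= 1)
  structure(list(vcf = vcf, traits = traits, gff = gff, outDir = outDir,
                 simulate = simulate, L = as.integer(L),
                 nHarmonics = as.integer(nHarmonics),
                 pcaCumThreshold = pcaCumThreshold, model = model,
                 nPerm = as.integer(nPerm), alpha = alpha,
                 window = window, clusterGap = clusterGap,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Run the full analysis pipeline
#'
#' Stages: data input (files or simulation) -> SNP filtering -> kinship,
#' LD decay and genotype PCA -> per-leaf-type single-leaf scans with
#' permutation thresholds -> multi-leaf SAD(1) likelihood-ratio scan with
#' its permutation threshold -> candidate regions (when gene models are
#' supplied). Returns a manifest of counts, parameters and results; when
#' \code{outDir} is set, tables are also written as TSV/JSON.
#'
#' @param cfg a \code{\link{runConfig}}.
#' @return list (the run manifest) with elements \code{counts},
#'   \code{singleLeaf}, \code{multiLeaf}, \code{thresholds},
#'   \code{regions}, \code{config}.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  manifest <- list(config = unclass(cfg)[setdiff(names(cfg), "simulate")],
                   counts = list())
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    geno <- simulateGenotypes(sim)
    ph <- simulatePhenotypes(geno, sim)
    pheno <- ph$phenotypes
    manifest$truth <- ph$truth
  } else {
    geno <- readGenotypeVcf(cfg$vcf)
    tt <- read.csv(cfg$traits)
    stopifnot(all(c("tree_id", "leaf_type") %in% colnames(tt)))
    traitCol <- setdiff(colnames(tt), c("tree_id", "leaf_type"))[1]
    wide <- reshape(tt[, c("tree_id", "leaf_type", traitCol)],
                    idvar = "tree_id", timevar = "leaf_type",
                    direction = "wide")
    wide <- wide[match(sampleIds(geno), wide$tree_id), ]
    pheno <- as.matrix(wide[, -1])
    manifest$counts$incomplete_trees <- sum(!complete.cases(pheno))
    keep <- complete.cases(pheno)
    pheno <- pheno[keep, , drop = FALSE]
    geno <- geno[keep, ]
  }
  manifest$counts$individuals <- nrow(pheno)
  manifest$counts$snps_input <- ncol(genotypeCalls(geno))

  flt <- filterSnps(geno)
  geno <- flt$genotypes
  manifest$counts$snps_filtered <- flt$report$n_kept
  manifest$filterReport <- flt$report

  K <- kinship(geno, method = "grm")
  pca <- genotypePca(geno, k = min(5L, nrow(pheno) - 2L))
  ld <- ldR2(geno)
  manifest$ldDecay <- if (!is.null(ld) && nrow(ld) >= 10)
    tryCatch(fitLdDecay(ld)[c("coef", "halfDecayDist", "flag")],
             error = function(e) list(flag = conditionMessage(e)))
  else list(flag = "too-few-pairs")
  manifest$structure <- list(pcaExplained = head(pca$explained, 5))

  spec <- switch(cfg$model,
    LM = singleLeafModel("LM"),
    Q = singleLeafModel("Q", covariates = pca$scores[, 1:2]),
    QK = singleLeafModel("QK", covariates = pca$scores[, 1:2], kinship = K))
  posNames <- colnames(pheno)
  single <- lapply(setNames(seq_len(ncol(pheno)), posNames), function(t) {
    y <- pheno[, t]
    scan <- assocScan(y, geno, spec)
    thr <- permutationThreshold(y, geno, spec, nPerm = cfg$nPerm,
                                alpha = cfg$alpha, seed = cfg$seed + t)
    scan$significant <- !is.na(scan$stat) & scan$stat^2 > thr$threshold
    list(scan = scan, threshold = thr$threshold,
         lambdaGC = attr(scan, "lambdaGC"))
  })
  manifest$singleLeaf <- single
  manifest$counts$single_leaf_significant <-
    sum(vapply(single, function(s) sum(s$scan$significant), integer(1)))

  mscan <- lrtScan(pheno, geno)
  mthr <- permutationThresholdMulti(pheno, geno, nPerm = cfg$nPerm,
                                    alpha = cfg$alpha, seed = cfg$seed + 99L)
  mscan$significant <- !is.na(mscan$lrt) & mscan$lrt > mthr$threshold
  manifest$multiLeaf <- list(scan = mscan, threshold = mthr$threshold)
  manifest$counts$multi_leaf_significant <- sum(mscan$significant)

  sig <- mscan[mscan$significant, c("chrom", "pos")]
  for (s in single)
    sig <- rbind(sig, s$scan[s$scan$significant, c("chrom", "pos")])
  sig <- unique(sig)
  if (!is.null(cfg$gff) && nrow(sig))
    manifest$regions <- candidateRegions(sig, cfg$gff,
                                         window = cfg$window,
                                         clusterGap = cfg$clusterGap)
  manifest$counts$significant_unique <- nrow(sig)

  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(mscan, file.path(cfg$outDir, "multi_leaf_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(single))
      utils::write.table(single[[nm]]$scan,
                         file.path(cfg$outDir,
                                   paste0("single_leaf_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(multi_leaf = mthr$threshold,
           single_leaf = lapply(single, `[[`, "threshold"),
           alpha = cfg$alpha, n_perm = cfg$nPerm, seed = cfg$seed),
      file.path(cfg$outDir, "thresholds.json"), auto_unbox = TRUE,
      digits = NA)
    if (!is.null(manifest$regions))
      writeCandidateBed(manifest$regions,
                        file.path(cfg$outDir, "candidate_regions.bed"))
  }
  manifest
}

#' Diagnostic figures from a run manifest
#'
#' Builds Manhattan and Q-Q plots for the multi-leaf scan and (when
#' present) the LD-decay scatter; returns ggplot objects.
#'
#' @param manifest output of \code{\link{runPipeline}}.
#' @return named list of ggplot objects.
#' @export
reportRun <- function(manifest) {
  ms <- manifest$multiLeaf$scan
  ms$index <- seq_len(nrow(ms))
  plots <- list()
  plots$manhattan <- ggplot2::ggplot(ms[!is.na(ms$lrt), ],
      ggplot2::aes(x = index, y = lrt, colour = chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = manifest$multiLeaf$threshold,
                        colour = "red") +
    ggplot2::labs(x = "SNP index", y = "LRT",
                  title = "Multi-leaf scan") +
    ggplot2::theme_minimal()
  lrt <- sort(na.omit(ms$lrt))
  dfq <- 4 * (2 - 1)   # reference df for a biallelic 2-group SNP
  qq <- data.frame(expected = qchisq(stats::ppoints(length(lrt)), df = dfq),
                   observed = lrt)
  plots$qq <- ggplot2::ggplot(qq, ggplot2::aes(expected, observed)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::labs(title = "Multi-leaf LRT Q-Q") +
    ggplot2::theme_minimal()
  plots
}
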