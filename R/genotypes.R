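# Genotype-side operations: VCF ingestion, the SNP quality filters, exact
# Hardy-Weinberg testing, kinship (GRM for the mixed model, KING-robust for
# QC), LD decay, genotype PCA for structure covariates, and the +/-100 kb
# candidate-region rule.

#' Read biallelic SNP genotypes from a VCF
#'
#' Keeps biallelic SNP records only (multi-allelic and indel records are
#' dropped and counted); GT is converted to 0/1/2 alternate-allele dosage,
#' \code{./.} to NA. Per-SNP MQ and mean DP are pulled from INFO when
#' present.
#'
#' @param path VCF file (plain or bgzipped).
#' @return a \linkS4class{GenotypeData}; the number of dropped records is
#'   in \code{attr(, "dropped")}.
#' @export
readGenotypeVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  fix <- vcfR::getFIX(v)
  snp <- nchar(fix[, "REF"]) == 1 & nchar(gsub(",.*", "", fix[, "ALT"])) == 1
  keep <- bi & snp
  dropped <- sum(!keep)
  if (dropped) message(dropped, " multi-allelic/non-SNP record(s) dropped")
  v <- v[keep, ]
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_real_, length(x))
    out[x %in% c("0/0")] <- 0
    out[x %in% c("0/1", "1/0")] <- 1
    out[x %in% c("1/1")] <- 2
    out
  }
  calls <- t(apply(gt, 1, code))          # SNP x sample -> transpose below
  calls <- t(calls)
  rownames(calls) <- colnames(gt)
  info <- function(tag) {
    x <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = tag)))
    if (all(is.na(x))) NULL else x
  }
  meta <- data.frame(chrom = fix[, "CHROM"],
                     pos = as.numeric(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"])
  mq <- info("MQ"); dp <- info("DP")
  if (!is.null(mq)) meta$mq <- mq
  if (!is.null(dp)) meta$depth <- dp
  o <- order(meta$chrom, meta$pos)
  g <- GenotypeData(calls[, o, drop = FALSE], meta[o, , drop = FALSE])
  attr(g, "dropped") <- dropped
  g
}

#' Write a GenotypeData as a minimal VCF
#'
#' Emits VCF 4.2 with GT calls (0/0, 0/1, 1/1, ./.) and INFO MQ/DP when the
#' metadata carry them.
#'
#' @param g a \linkS4class{GenotypeData}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeGenotypeVcf <- function(g, path) {
  meta <- snpMeta(g)
  calls <- genotypeCalls(g)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
               "##INFO=<ID=DP,Number=1,Type=Float,Description=\"Mean depth\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sampleIds(g)), collapse = "\t")), con)
  gtStr <- matrix(".\\.", nrow(calls), ncol(calls))
  gtStr <- matrix(c("0/0", "0/1", "1/1")[calls + 1], nrow(calls))
  gtStr[is.na(calls)] <- "./."
  info <- rep(".", nrow(meta))
  if (all(c("mq", "depth") %in% colnames(meta)))
    info <- sprintf("MQ=%g;DP=%g", meta$mq, meta$depth)
  lines <- vapply(seq_len(nrow(meta)), function(j)
    paste(c(meta$chrom[j], meta$pos[j], paste0("snp", j), meta$ref[j],
            meta$alt[j], ".", "PASS", info[j], "GT", gtStr[, j]),
          collapse = "\t"), character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Levene's exact conditional test: given the allele counts, the
#' heterozygote count is enumerated over its conditional distribution and
#' the two-sided p-value is the total probability of outcomes no more
#' likely than the observed one (mid-p not applied).
#'
#' @param nAA,nAa,naa genotype counts (non-negative, sum >= 1).
#' @return p-value in (0, 1].
#' @examples
#' hweExactTest(1, 0, 1)    # 1/3
#' hweExactTest(25, 50, 25) # 1 (conditional mode)
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  if (any(c(nAA, nAa, naa) < 0) || nAA + nAa + naa < 1)
    stop("counts must be non-negative with a positive total")
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  hets <- seq(nA %% 2, min(nA, na), by = 2)
  # log P(het) up to a constant: conditional on allele counts,
  # P ∝ 2^het / (hAA! het! haa!)
  lp <- hets * log(2) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((na - hets) / 2)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  pObs <- pr[match(nAa, hets)]
  sum(pr[pr <= pObs * (1 + 1e-10)])
}

#' Apply the SNP quality filters
#'
#' Keeps SNPs with mapping quality > \code{mq}, missing rate <
#' \code{missing}, minor allele frequency >= \code{maf}, mean depth >
#' \code{depth}, and exact Hardy-Weinberg p > \code{hwe}. Missing MQ/depth
#' metadata skip those two filters with a warning.
#'
#' @param g a \linkS4class{GenotypeData}.
#' @param mq,missing,maf,depth,hwe thresholds (defaults 20, 0.5, 0.05, 40,
#'   0.05).
#' @return list with \code{genotypes} (filtered
#'   \linkS4class{GenotypeData}) and \code{report} (SNPs failing each
#'   criterion, and totals).
#' @export
filterSnps <- function(g, mq = 20, missing = 0.5, maf = 0.05, depth = 40,
                       hwe = 0.05) {
  calls <- genotypeCalls(g)
  meta <- snpMeta(g)
  m <- ncol(calls)
  failMq <- failDepth <- rep(FALSE, m)
  if ("mq" %in% colnames(meta)) failMq <- !(meta$mq > mq)
  else warning("no mapping-quality metadata; MQ filter skipped")
  if ("depth" %in% colnames(meta)) failDepth <- !(meta$depth > depth)
  else warning("no depth metadata; depth filter skipped")
  missRate <- colMeans(is.na(calls))
  failMiss <- !(missRate < missing)
  af <- colMeans(calls, na.rm = TRUE) / 2
  mafv <- pmin(af, 1 - af)
  failMaf <- !(mafv >= maf)
  hweP <- vapply(seq_len(m), function(j) {
    x <- calls[, j]
    x <- x[!is.na(x)]
    if (!length(x)) return(0)
    hweExactTest(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))
  failHwe <- !(hweP > hwe)
  keep <- !(failMq | failMiss | failMaf | failDepth | failHwe)
  list(genotypes = g[, keep],
       report = list(n_input = m, n_kept = sum(keep),
                     removed_mq = sum(failMq),
                     removed_missing = sum(failMiss),
                     removed_maf = sum(failMaf),
                     removed_depth = sum(failDepth),
                     removed_hwe = sum(failHwe),
                     removed_total = sum(!keep)))
}

#' Kinship estimation
#'
#' \code{method = "grm"}: centered, standardized realized relationship
#' matrix Z Z'/m (per-SNP mean imputation of missing calls; positive
#' semi-definite; the K of the mixed model). \code{method = "king"}:
#' KING-robust pairwise kinship for QC; values for unrelated pairs scatter
#' around 0 and are not a valid model covariance.
#'
#' @param x a \linkS4class{GenotypeData}.
#' @param method "grm" (default) or "king".
#' @return a \linkS4class{KinshipMatrix}.
#' @export
setGeneric("kinship", function(x, method = "grm") standardGeneric("kinship"))

#' @rdname kinship
#' @export
setMethod("kinship", "GenotypeData", function(x, method = "grm") {
  method <- match.arg(method, c("grm", "king"))
  G <- genotypeCalls(x)
  if (nrow(G) < 2) stop("need at least 2 individuals")
  if (method == "grm") {
    af <- colMeans(G, na.rm = TRUE) / 2
    poly <- af > 0 & af < 1 & !is.na(af)
    if (!any(poly)) stop("no polymorphic SNPs")
    G <- G[, poly, drop = FALSE]
    af <- af[poly]
    Z <- sweep(G, 2, 2 * af)
    Z[is.na(Z)] <- 0                       # mean imputation after centering
    Z <- sweep(Z, 2, sqrt(2 * af * (1 - af)), "/")
    K <- tcrossprod(Z) / ncol(Z)
    return(new("KinshipMatrix", values = (K + t(K)) / 2, estimator = "grm"))
  }
  H <- (G == 1); A <- (G == 0); B <- (G == 2); M <- !is.na(G)
  H[is.na(H)] <- FALSE; A[is.na(A)] <- FALSE; B[is.na(B)] <- FALSE
  storage.mode(H) <- storage.mode(A) <- storage.mode(B) <- "double"
  storage.mode(M) <- "double"
  nHH <- tcrossprod(H)
  nOpp <- tcrossprod(A, B) + tcrossprod(B, A)
  nHet <- H %*% t(M)                       # hets in i over SNPs typed in j
  den <- nHet + t(nHet)
  K <- (nHH - 2 * nOpp) / den
  diag(K) <- 0.5
  new("KinshipMatrix", values = (K + t(K)) / 2, estimator = "king")
})

#' Pairwise LD (r-squared) within a distance window
#'
#' Squared Pearson correlation of genotype dosages for all SNP pairs on the
#' same chromosome within \code{maxDist} bp, pairwise-complete over missing
#' calls; monomorphic pairs are skipped.
#'
#' @param g a \linkS4class{GenotypeData}.
#' @param maxDist window in bp (default 1e6, i.e. 1,000 kb).
#' @return data.frame: \code{chrom}, \code{pos1}, \code{pos2}, \code{dist},
#'   \code{r2}.
#' @export
ldR2 <- function(g, maxDist = 1e6) {
  calls <- genotypeCalls(g)
  meta <- snpMeta(g)
  res <- lapply(split(seq_len(ncol(calls)), meta$chrom), function(ix) {
    if (length(ix) < 2) return(NULL)
    C2 <- suppressWarnings(
      cor(calls[, ix, drop = FALSE], use = "pairwise.complete.obs"))^2
    pr <- which(upper.tri(C2), arr.ind = TRUE)
    d <- abs(meta$pos[ix[pr[, 2]]] - meta$pos[ix[pr[, 1]]])
    ok <- d <= maxDist & is.finite(C2[pr])
    if (!any(ok)) return(NULL)
    data.frame(chrom = meta$chrom[ix[1]],
               pos1 = meta$pos[ix[pr[ok, 1]]],
               pos2 = meta$pos[ix[pr[ok, 2]]],
               dist = d[ok], r2 = C2[pr][ok])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Fit an LD decay curve and its baseline crossing
#'
#' Non-linear least squares of r2(d) = a * exp(-b * d) + c (the default
#' empirical exponential; \code{model = "hill"} uses the Hill-Weir drift
#' expectation instead). Reports the distance at which the fitted curve
#' crosses \code{baselineR^2} (the convention of quoting the baseline on
#' the r scale).
#'
#' @param r2tab data.frame from \code{\link{ldR2}} (needs \code{dist},
#'   \code{r2}; >= 10 pairs).
#' @param baselineR LD baseline on the correlation (r) scale, default 0.1.
#' @param model "exponential" (default) or "hill".
#' @param n sample size, required for \code{model = "hill"}.
#' @return list with \code{coef}, \code{halfDecayDist} (bp at the baseline
#'   crossing; NA with \code{flag = "no-decay"} when the curve never
#'   reaches it), \code{model}, \code{fit}.
#' @export
fitLdDecay <- function(r2tab, baselineR = 0.1, model = "exponential",
                       n = NULL) {
  model <- match.arg(model, c("exponential", "hill"))
  if (nrow(r2tab) < 10) stop("need at least 10 SNP pairs")
  d <- r2tab$dist; r2 <- r2tab$r2
  target <- baselineR^2
  if (model == "exponential") {
    c0 <- quantile(r2[d > quantile(d, 0.8)], 0.5, names = FALSE)
    a0 <- max(mean(r2[d < quantile(d, 0.1)]) - c0, 0.01)
    b0 <- 1 / max(median(d), 1)
    fit <- tryCatch(
      minpack.lm::nlsLM(r2 ~ a * exp(-b * d) + c,
                        start = list(a = a0, b = b0, c = c0),
                        lower = c(0, 0, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) stop("LD decay fit did not converge: ",
                               conditionMessage(e)))
    cf <- coef(fit)
    noDecay <- cf["b"] * max(d) < 1e-6
    cross <- if (!noDecay && cf["a"] > 0 && target > cf["c"] &&
                 target < cf["a"] + cf["c"])
      -log((target - cf["c"]) / cf["a"]) / cf["b"]
    else NA_real_
    return(list(coef = cf, halfDecayDist = unname(cross), model = model,
                flag = if (noDecay) "no-decay" else
                  if (is.na(cross)) "baseline-not-crossed" else "ok",
                fit = fit))
  }
  if (is.null(n)) stop("model = 'hill' needs the sample size n")
  hill <- function(d, rho) {
    C <- rho * d
    (10 + C) / ((2 + C) * (11 + C)) *
      (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
  }
  fit <- minpack.lm::nlsLM(r2 ~ hill(d, rho), start = list(rho = 1e-4),
                           lower = 0)
  rho <- coef(fit)["rho"]
  dd <- seq(min(d), max(d), length.out = 5000)
  hv <- hill(dd, rho)
  cross <- if (any(hv <= target)) dd[which(hv <= target)[1]] else NA_real_
  list(coef = c(rho = unname(rho)), halfDecayDist = unname(cross),
       model = model, flag = if (is.na(cross)) "baseline-not-crossed" else "ok",
       fit = fit)
}

#' Genotype PCA for population-structure covariates
#'
#' PCA of the standardized (per-SNP centered/scaled, mean-imputed) genotype
#' matrix; the top scores serve as the Q covariates of the association
#' models.
#'
#' @param g a \linkS4class{GenotypeData}.
#' @param k number of components (default 10).
#' @return list with \code{scores} (n x k), \code{explained} (variance
#'   fractions, all components).
#' @export
genotypePca <- function(g, k = 10L) {
  G <- genotypeCalls(g)
  af <- colMeans(G, na.rm = TRUE) / 2
  poly <- af > 0 & af < 1 & !is.na(af)
  G <- G[, poly, drop = FALSE]; af <- af[poly]
  Z <- sweep(G, 2, 2 * af)
  Z[is.na(Z)] <- 0
  Z <- sweep(Z, 2, sqrt(2 * af * (1 - af)), "/")
  if (k > min(dim(Z)) - 1) stop("k exceeds the matrix rank")
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE], explained = frac)
}

#' Candidate regions around significant SNPs and their genes
#'
#' Significant SNPs closer than \code{clusterGap} are merged into one
#' region spanning the left- to right-most SNP; isolated SNPs get a
#' pos +/- \code{window} region. Genes overlapping each region are
#' reported.
#'
#' @param sigSnps data.frame with \code{chrom}, \code{pos} of significant
#'   SNPs.
#' @param genes gene intervals: a \code{GRanges} or a GFF3 path (rows with
#'   type "gene" are used; gene identifiers from \code{ID} or \code{Name}).
#' @param window flank for isolated SNPs in bp (default 1e5).
#' @param clusterGap maximum gap for merging SNPs in bp (default 5e4).
#' @return data.frame of regions (\code{chrom}, \code{start}, \code{end},
#'   \code{n_snps}) with a comma-separated \code{genes} column.
#' @export
candidateRegions <- function(sigSnps, genes, window = 1e5,
                             clusterGap = 5e4) {
  if (!nrow(sigSnps))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_snps = integer(),
                      genes = character()))
  if (is.character(genes)) {
    gr <- rtracklayer::import(genes)
    if ("type" %in% colnames(S4Vectors::mcols(gr)) &&
        any(gr$type == "gene"))
      gr <- gr[gr$type == "gene"]
    genes <- gr
  }
  regions <- do.call(rbind, lapply(split(sigSnps, sigSnps$chrom),
                                   function(s) {
    pos <- sort(s$pos)
    cl <- cumsum(c(1, diff(pos) > clusterGap))
    do.call(rbind, lapply(split(pos, cl), function(pp) {
      if (length(pp) == 1)
        data.frame(chrom = s$chrom[1], start = max(1, pp - window),
                   end = pp + window, n_snps = 1L)
      else
        data.frame(chrom = s$chrom[1], start = min(pp), end = max(pp),
                   n_snps = length(pp))
    }))
  }))
  rownames(regions) <- NULL
  rr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start, regions$end))
  ov <- GenomicRanges::findOverlaps(rr, genes)
  ids <- if (!is.null(genes$ID)) genes$ID
  else if (!is.null(genes$Name)) genes$Name
  else paste0("gene", seq_along(genes))
  regions$genes <- vapply(seq_along(rr), function(i) {
    hit <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]
    paste(unique(ids[hit]), collapse = ",")
  }, character(1))
  regions
}

#' Write candidate regions as BED (0-based half-open)
#' @param regions data.frame from \code{\link{candidateRegions}}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeCandidateBed <- function(regions, path) {
  bed <- data.frame(regions$chrom, as.integer(regions$start) - 1L,
                    as.integer(regions$end), regions$genes)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
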