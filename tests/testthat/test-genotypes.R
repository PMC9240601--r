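test_that("VCF writing and reading round-trip genotype codes", {
  tmp <- tempfile(fileext = ".vcf")
  calls <- matrix(c(0, 1, 2,  2, NA, 0,  1, 1, 1), 3, 3)
  g <- toyGenotypes(calls)
  writeGenotypeVcf(g, tmp)
  g2 <- readGenotypeVcf(tmp)
  expect_equal(unname(genotypeCalls(g2)), unname(calls))
  expect_equal(snpMeta(g2)$pos, snpMeta(g)$pos)
  expect_equal(snpMeta(g2)$mq, rep(60, 3))
  # a multi-allelic record is dropped and counted
  lines <- readLines(tmp)
  bad <- "chr1\t5000\tm\tA\tT,G\t.\tPASS\t.\tGT\t1/2\t0/0\t0/1"
  writeLines(append(lines, bad), tmp)
  expect_message(g3 <- readGenotypeVcf(tmp), "dropped")
  expect_equal(ncol(genotypeCalls(g3)), 3)
  expect_equal(attr(g3, "dropped"), 1)
})

test_that("HWE exact test reproduces hand-computed conditional cases", {
  expect_equal(hweExactTest(1, 0, 1), 1 / 3, tolerance = 1e-12)
  expect_equal(hweExactTest(25, 50, 25), 1)
  expect_lt(hweExactTest(0, 100, 0), 1e-10)
  expect_error(hweExactTest(0, 0, 0), "positive total")
})

test_that("HWE exact test equals the combinatorial enumeration oracle", {
  # oracle: count allele-to-pair assignments directly
  oracle <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    nA <- 2 * nAA + nAa
    hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
    lp <- lchoose(n, hets) + lchoose(n - hets, (nA - hets) / 2) +
      hets * log(2) - lchoose(2 * n, nA)
    pr <- exp(lp); pr <- pr / sum(pr)
    sum(pr[pr <= pr[match(nAa, hets)] * (1 + 1e-10)])
  }
  for (n in c(3, 10, 25, 50)) {
    for (nAA in 0:n) for (nAa in 0:(n - nAA)) {
      naa <- n - nAA - nAa
      expect_equal(hweExactTest(nAA, nAa, naa), oracle(nAA, nAa, naa),
                   tolerance = 1e-9)
    }
  }
})

test_that("SNP filters enforce every criterion and are idempotent", {
  set.seed(3)
  n <- 60
  good <- rbinom(n, 2, 0.3)
  lowMaf <- rbinom(n, 2, 0.02)
  manyMiss <- good; manyMiss[1:36] <- NA      # 60% missing
  hweBad <- rep(1, n)                          # all heterozygous
  calls <- cbind(good, lowMaf, manyMiss, hweBad, good)
  meta <- data.frame(chrom = "chr1", pos = 1:5 * 100, ref = "A", alt = "T",
                     mq = c(60, 60, 60, 60, 10), depth = c(50, 50, 50, 50, 50))
  g <- GenotypeData(calls, meta)
  f <- filterSnps(g)
  expect_equal(f$report$n_kept, 1)
  expect_gte(f$report$removed_maf, 1)
  expect_gte(f$report$removed_missing, 1)
  expect_gte(f$report$removed_hwe, 1)
  expect_equal(f$report$removed_mq, 1)
  f2 <- filterSnps(f$genotypes)
  expect_equal(f2$report$removed_total, 0)     # idempotent
  # missing metadata skips those filters with a warning
  g2 <- GenotypeData(calls[, 1, drop = FALSE],
                     meta[1, c("chrom", "pos", "ref", "alt")])
  w <- capture_warnings(f3 <- filterSnps(g2))
  expect_match(w, "MQ filter skipped", all = FALSE)
  expect_match(w, "depth filter skipped", all = FALSE)
})

test_that("GRM kinship: duplicates, independence, HWE diagonal", {
  set.seed(5)
  cfg <- simConfig(n_individuals = 30, n_snps = 50000,
                   maf_range = c(0.1, 0.5), seed = 23)
  g <- simulateGenotypes(cfg)
  K <- kinshipValues(kinship(g, "grm"))
  expect_lt(max(abs(K[upper.tri(K)])), 3 / sqrt(50000) * 3 + 0.02)
  expect_equal(mean(diag(K)), 1, tolerance = 0.05)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)                    # PSD
  # duplicated individual
  calls <- genotypeCalls(g)[c(1, 1, 2:10), 1:5000]
  gd <- toyGenotypes(calls, pos = 1:5000)
  K2 <- kinshipValues(kinship(gd, "grm"))
  expect_equal(K2[1, 2], K2[1, 1], tolerance = 1e-10)
})

test_that("KING-robust kinship identifies parent-offspring pairs", {
  set.seed(9)
  m <- 5000
  p <- runif(m, 0.1, 0.5)
  momA <- rbinom(m, 1, p); momB <- rbinom(m, 1, p)
  dadA <- rbinom(m, 1, p); dadB <- rbinom(m, 1, p)
  child <- ifelse(rbinom(m, 1, 0.5) == 1, momA, momB) +
    ifelse(rbinom(m, 1, 0.5) == 1, dadA, dadB)
  G <- rbind(momA + momB, dadA + dadB, child,
             t(replicate(4, rbinom(m, 2, p))))
  K <- kinshipValues(kinship(toyGenotypes(G, pos = 1:m), "king"))
  expect_lt(abs(K[1, 3] - 0.25), 0.02)
  expect_lt(abs(K[2, 3] - 0.25), 0.02)
  expect_lt(abs(K[1, 2]), 0.02)
  expect_equal(K[1, 1], 0.5)
})

test_that("LD r2 is a correlation: bounds, symmetry, relabeling", {
  set.seed(11)
  n <- 10000
  x <- rbinom(n, 2, 0.3)
  indep <- sapply(1:40, function(i) rbinom(n, 2, 0.3))
  calls <- cbind(x, x, 2 - x, indep)
  g <- toyGenotypes(calls, pos = (1:ncol(calls)) * 1000)
  tab <- ldR2(g)
  expect_true(all(tab$r2 >= 0 & tab$r2 <= 1 + 1e-12))
  dup <- tab[tab$pos1 == 1000 & tab$pos2 == 2000, "r2"]
  expect_equal(dup, 1, tolerance = 1e-12)
  flip <- tab[tab$pos1 == 1000 & tab$pos2 == 3000, "r2"]
  expect_equal(flip, 1, tolerance = 1e-12)     # allele relabeling 0<->2
  nullPairs <- tab[tab$pos1 > 3000 & tab$pos2 > 3000, "r2"]
  expect_lt(mean(nullPairs), 0.001)            # null r2 ~ 1/n
  # distance window respected
  tabW <- ldR2(g, maxDist = 5000)
  expect_true(all(tabW$dist <= 5000))
})

test_that("LD decay fit recovers exponential parameters and flags no-decay", {
  set.seed(13)
  d <- runif(3000, 0, 5e5)
  r2 <- 0.5 * exp(-1e-5 * d) + 0.05 + rnorm(3000, sd = 0.01)
  fit <- fitLdDecay(data.frame(dist = d, r2 = pmax(r2, 0)))
  expect_lt(abs(fit$coef["a"] / 0.5 - 1), 0.1)
  expect_lt(abs(fit$coef["b"] / 1e-5 - 1), 0.1)
  expect_lt(abs(fit$coef["c"] / 0.05 - 1), 0.1)
  # lowering the baseline pushes the crossing farther out
  fitLow <- fitLdDecay(data.frame(dist = d, r2 = pmax(r2, 0)),
                       baselineR = 0.32)
  fitHigh <- fitLdDecay(data.frame(dist = d, r2 = pmax(r2, 0)),
                        baselineR = 0.45)
  expect_gt(fitLow$halfDecayDist, fitHigh$halfDecayDist)
  # constant r2: no decay, crossing undefined
  flat <- fitLdDecay(data.frame(dist = d, r2 = rep(0.3, 3000) +
                                  rnorm(3000, sd = 1e-4)))
  expect_true(flat$flag %in% c("no-decay", "baseline-not-crossed"))
  expect_true(is.na(flat$halfDecayDist))
  expect_error(fitLdDecay(data.frame(dist = 1:5, r2 = runif(5))), "10")
})

test_that("genotype PCA separates simulated subpopulations", {
  cfg <- simConfig(n_individuals = 200, n_snps = 2000, fst = 0.1, seed = 4)
  g <- simulateGenotypes(cfg)
  sub <- attr(g, "subpop")
  pc <- genotypePca(g, k = 3)
  x <- pc$scores[, 1]
  sil <- mean(vapply(seq_along(x), function(i) {
    a <- mean(abs(x[i] - x[setdiff(which(sub == sub[i]), i)]))
    b <- mean(abs(x[i] - x[sub != sub[i]]))
    (b - a) / max(a, b)
  }, numeric(1)))
  expect_gt(sil, 0.5)
  expect_true(all(diff(pc$explained) <= 1e-12))
  # permutation equivariance (up to component sign)
  perm <- sample(200)
  g2 <- g[perm, ]
  pc2 <- genotypePca(g2, k = 3)
  for (k in 1:3) {
    s <- sign(cor(pc$scores[perm, k], pc2$scores[, k]))
    expect_equal(pc$scores[perm, k], s * pc2$scores[, k],
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  expect_error(genotypePca(g[1:5, ], k = 50), "rank")
})

test_that("candidate regions merge clusters and respect the window", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
    "chr1\ttest\tgene\t200000\t210000\t.\t+\t.\tID=geneA",
    "chr1\ttest\tgene\t400000\t410000\t.\t+\t.\tID=geneB"), gff)
  # isolated SNP at 150 kb, window 100 kb -> geneA overlaps, geneB does not
  r1 <- candidateRegions(data.frame(chrom = "chr1", pos = 150000), gff)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$genes, "geneA")
  # two SNPs 5 kb apart with 50 kb gap -> one merged region
  r2 <- candidateRegions(data.frame(chrom = "chr1",
                                    pos = c(100000, 105000)), gff)
  expect_equal(nrow(r2), 1)
  expect_equal(r2$start, 100000)
  expect_equal(r2$end, 105000)
  expect_equal(r2$n_snps, 2L)
  # empty input -> empty output
  expect_equal(nrow(candidateRegions(data.frame(chrom = character(),
                                                pos = numeric()), gff)), 0)
  # BED export is 0-based half-open
  bed <- tempfile(fileext = ".bed")
  writeCandidateBed(r1, bed)
  fields <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(as.numeric(fields[2]), r1$start - 1)
  expect_equal(as.numeric(fields[3]), r1$end)
})
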