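test_that("SAD(1) covariance matches the antedependence recursion", {
  expect_equal(sad1Covariance(Sad1Params(0, 1), 4), diag(4))
  expect_equal(sad1Covariance(Sad1Params(0.5, 1), 2),
               matrix(c(1, 0.5, 0.5, 1.25), 2))
  for (phi in c(-1.5, -0.3, 0, 0.7, 1.2)) {
    S <- sad1Covariance(Sad1Params(phi, 2.3), 4)
    expect_equal(S, sadCovBrute(phi, 2.3, 4))
    expect_silent(chol(S))   # positive definite for any phi
  }
  expect_error(Sad1Params(0.5, -1), "nu2")
})

test_that("null fit log-likelihood equals brute-force MVN evaluation", {
  set.seed(11)
  for (r in 1:20) {
    phi <- runif(1, -1, 1.4); nu2 <- exp(runif(1, -1, 1))
    Y <- MASS::mvrnorm(60, rnorm(4), sad1Covariance(Sad1Params(phi, nu2)))
    f <- fitSadNull(Y)
    expect_equal(f$mean, colMeans(Y))
    S <- sad1Covariance(f$params)
    expect_equal(f$logLik, mvnLogLik(Y, f$mean, S), tolerance = 1e-8)
    # exact stationarity: no nearby (phi, nu2) does better
    for (d in list(c(1e-3, 0), c(-1e-3, 0), c(0, 1e-3), c(0, -1e-3))) {
      S2 <- sad1Covariance(Sad1Params(f$params@phi + d[1],
                                      f$params@nu2 * (1 + d[2])))
      expect_lte(mvnLogLik(Y, f$mean, S2), f$logLik + 1e-10)
    }
  }
})

test_that("null fit recovers the generating SAD(1) parameters", {
  set.seed(21)
  est <- replicate(10, {
    Y <- MASS::mvrnorm(2000, rep(0, 4), sad1Covariance(Sad1Params(0.6, 2)))
    f <- fitSadNull(Y)
    c(f$params@phi, f$params@nu2)
  })
  expect_lt(abs(mean(est[1, ]) - 0.6), 0.05)
  expect_lt(abs(mean(est[2, ]) / 2 - 1), 0.10)
})

test_that("degenerate phenotypes are rejected", {
  Y <- matrix(1, 20, 4)
  expect_error(fitSadNull(Y), "degenerate")
  expect_error(fitSadNull(Y[1:3, ]), "at least 5")
})

test_that("full fit: group means are exact MLEs and nesting holds", {
  set.seed(31)
  Y <- MASS::mvrnorm(120, rep(0, 4), sad1Covariance(Sad1Params(0.4, 1)))
  g <- rbinom(120, 2, 0.4)
  f <- fitSadFull(Y, g)
  for (k in seq_along(f$groups))
    expect_equal(unname(f$groupMeans[k, ]),
                 unname(colMeans(Y[g == f$groups[k], ])))
  expect_gte(f$logLik, f$logLikNull)
  expect_gte(f$lrt, 0)
  expect_equal(f$logLik,
               mvnLogLik(Y[g %in% f$groups, ] -
                           f$groupMeans[match(g[g %in% f$groups], f$groups), ],
                         rep(0, 4), sad1Covariance(f$params)),
               tolerance = 1e-8)
  # identical group means => LRT 0
  Yc <- Y - f$groupMeans[match(g, f$groups), ]
  expect_lt(fitSadFull(Yc, g)$lrt, 1e-8)
  # monomorphic SNP is skipped
  expect_error(fitSadFull(Y, rep(1, 120)), "fewer than 2")
})

test_that("LRT scan matches single-SNP fits and is invariant to shifts", {
  set.seed(41)
  cfg <- simConfig(n_individuals = 150, n_snps = 40, seed = 8)
  g <- simulateGenotypes(cfg)
  Y <- simulatePhenotypes(g, cfg)$phenotypes
  sc <- lrtScan(Y, g)
  expect_true(all(sc$lrt >= 0, na.rm = TRUE))
  G <- genotypeCalls(g)
  for (j in c(1, 7, 23)) {
    f <- fitSadFull(Y, G[, j])
    expect_equal(sc$lrt[j], f$lrt, tolerance = 1e-8)
    expect_equal(sc$phi[j], f$params@phi, tolerance = 1e-8)
    expect_equal(sc$nu2[j], f$params@nu2, tolerance = 1e-8)
  }
  # adding a constant 4-vector changes nothing
  sc2 <- lrtScan(sweep(Y, 2, c(5, -3, 2, 100), "+"), g)
  expect_equal(sc2$lrt, sc$lrt, tolerance = 1e-7)
  # duplicated SNP columns give identical statistics
  G2 <- cbind(G[, 1], G[, 1])
  sc3 <- lrtScan(Y, G2)
  expect_equal(sc3$lrt[1], sc3$lrt[2])
})

test_that("permuted phenotypes give approximately chi-square LRTs", {
  set.seed(51)
  cfg <- simConfig(n_individuals = 400, n_snps = 300,
                   maf_range = c(0.3, 0.5), seed = 3)
  g <- simulateGenotypes(cfg)
  Y <- simulatePhenotypes(g, cfg)$phenotypes[sample(400), ]
  sc <- lrtScan(Y, g)
  l3 <- sort(sc$lrt[sc$J == 3 & !is.na(sc$lrt)])
  q <- qchisq(ppoints(length(l3)), df = 8)  # 4 * (J - 1)
  slope <- unname(coef(lm(l3 ~ 0 + q)))
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
})

test_that("multi-leaf permutation threshold behaves like a max quantile", {
  set.seed(61)
  cfg <- simConfig(n_individuals = 120, n_snps = 60, seed = 12)
  g <- simulateGenotypes(cfg)
  Y <- simulatePhenotypes(g, cfg)$phenotypes
  thr <- permutationThresholdMulti(Y, g, nPerm = 120, alpha = 0.05, seed = 2)
  thr2 <- permutationThresholdMulti(Y, g, nPerm = 120, alpha = 0.05, seed = 2)
  expect_identical(thr$threshold, thr2$threshold)    # seeded reproducibility
  thr20 <- quantile(thr$maxStats, 0.80)
  expect_gte(thr$threshold, unname(thr20))           # monotone in alpha
  expect_error(permutationThresholdMulti(Y, g, nPerm = 50), "100")
})

test_that("planted group-mean shifts are detected with high power", {
  set.seed(71)
  hits <- 0
  for (r in 1:30) {
    x <- rep(0:1, each = 300)
    Y <- MASS::mvrnorm(600, rep(0, 4), sad1Covariance(Sad1Params(0.3, 1)))
    Y <- Y + outer(x, c(0, 0, 1, 1))
    f <- fitSadFull(Y, x)
    if (f$lrt > qchisq(0.95, df = 4)) hits <- hits + 1
  }
  expect_gte(hits / 30, 0.9)
})

test_that("PVE matches intuition and the additive closed form", {
  # deterministic genotype -> 100%
  x <- rep(c(0, 1, 2), each = 10)
  Y <- outer(x, c(1, 2, 3, 4))
  fit <- list(groups = 0:2, groupMeans = outer(0:2, c(1, 2, 3, 4)),
              nj = rep(10, 3))
  expect_equal(pve(fit, Y, x)$max, 100)
  # identical group means -> 0
  fit0 <- list(groups = 0:2, groupMeans = matrix(1, 3, 4), nj = rep(10, 3))
  set.seed(81)
  expect_equal(pve(fit0, matrix(rnorm(120), 30, 4) + 1, x)$perPosition,
               rep(0, 4), tolerance = 1e-10)
  # HWE additive closed form 2p(1-p)a^2 / (2p(1-p)a^2 + sigma^2)
  p <- 0.3; a <- 0.5
  x <- rbinom(5000, 2, p)
  Y <- MASS::mvrnorm(5000, rep(0, 4), diag(4))
  Y[, 3] <- Y[, 3] + a * x
  f <- fitSadFull(Y, x)
  expected <- 100 * 2 * p * (1 - p) * a^2 / (2 * p * (1 - p) * a^2 + 1)
  got <- pve(f, Y, x)$perPosition[3]
  expect_lt(abs(got / expected - 1), 0.1)
})
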