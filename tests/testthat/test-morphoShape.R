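test_that("radial semi-landmarks respect circle and ellipse geometry", {
  sl <- radialSemilandmarks(circleOutline(400), L = 4)
  expect_equal(sqrt(rowSums(sweep(sl, 2, attr(sl, "center"))^2)),
               rep(1, 4), tolerance = 1e-3, ignore_attr = TRUE)
  # ellipse (2, 1), start on the major axis: radii (2, 1, 2, 1)
  sl2 <- radialSemilandmarks(ellipseOutline(2, 1, 800), L = 4)
  r <- sqrt(rowSums(sweep(sl2, 2, attr(sl2, "center"))^2))
  expect_equal(r, c(2, 1, 2, 1), tolerance = 1e-3, ignore_attr = TRUE)
  # all radii positive for star-shaped leaf curves of any class
  for (li in c(0.8, 1.5, 3, 5)) {
    o <- simulateOutlines(data.frame(tree_id = "t", leaf_type = "unassigned",
                                     LI = li))[[1]]
    slk <- radialSemilandmarks(o, L = 100)
    expect_true(all(sqrt(rowSums(sweep(slk, 2,
                                       attr(slk, "center"))^2)) > 0))
    expect_false(attr(slk, "flagged"))
  }
})

test_that("Procrustes alignment removes similarity transforms", {
  set.seed(4)
  base <- radialSemilandmarks(
    simulateOutlines(data.frame(tree_id = "t", leaf_type = "unassigned",
                                LI = 2))[[1]], L = 50)
  ang <- 0.7; R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  copy <- sweep(base %*% R * 3.2, 2, c(10, -4), "+")
  al <- procrustesNormalize(list(unclass(base), unclass(copy)))
  expect_lt(max(abs(al[[1]] - al[[2]])), 1e-8)
  # one-element set: centered, unit size, no rotation applied
  one <- procrustesNormalize(list(unclass(base)))
  expect_equal(colMeans(one[[1]]), c(0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sqrt(sum(one[[1]]^2)), 1, tolerance = 1e-12)
  # idempotence
  set.seed(5)
  shapes <- lapply(1:5, function(i)
    unclass(base) + matrix(rnorm(100, sd = 0.02), 50, 2))
  al1 <- procrustesNormalize(shapes)
  al2 <- procrustesNormalize(lapply(al1, identity))
  for (i in 1:5) expect_lt(max(abs(al1[[i]] - al2[[i]])), 1e-8)
  expect_error(procrustesNormalize(list(matrix(1, 10, 2))), "degenerate")
})

# independent oracle: exact segment-wise integration of the Fourier
# projection integrals (2/T) \int x(t) cos(2 pi n t / T) dt for the
# piecewise-linear contour (antiderivative form, a different derivation
# from the package's first-derivative formulation)
efaOracle <- function(p, nh) {
  n <- nrow(p); i2 <- c(2:n, 1)
  d <- p[i2, ] - p
  dt <- sqrt(rowSums(d^2))
  t1 <- cumsum(dt); t0 <- c(0, t1[-n]); T <- t1[n]
  coefs <- matrix(0, nh, 4)
  for (h in seq_len(nh)) {
    w <- 2 * pi * h / T
    segInt <- function(x0, slope, t0, t1, fun) {
      if (fun == "cos") {
        (x0 - slope * t0) * (sin(w * t1) - sin(w * t0)) / w +
          slope * ((cos(w * t1) - cos(w * t0)) / w^2 +
                     (t1 * sin(w * t1) - t0 * sin(w * t0)) / w)
      } else {
        -(x0 - slope * t0) * (cos(w * t1) - cos(w * t0)) / w +
          slope * ((sin(w * t1) - sin(w * t0)) / w^2 -
                     (t1 * cos(w * t1) - t0 * cos(w * t0)) / w)
      }
    }
    for (k in 1:2) {
      slope <- d[, k] / dt
      a <- sum(segInt(p[, k], slope, t0, t1, "cos")) * 2 / T
      b <- sum(segInt(p[, k], slope, t0, t1, "sin")) * 2 / T
      coefs[h, (k - 1) * 2 + 1:2] <- c(a, b)
    }
  }
  coefs[, c(1, 2, 3, 4)]
}

test_that("elliptic Fourier coefficients match exact integration", {
  th <- seq(0, 2 * pi, length.out = 120)[-120]
  blob <- cbind(cos(th) * (1 + 0.3 * cos(2 * th)),
                sin(th) * (1 - 0.2 * sin(3 * th)))
  d <- efaFit(blob, 12)
  expect_equal(unname(efHarmonics(d)), unname(efaOracle(blob, 12)),
               tolerance = 1e-8)
})

test_that("EFA basics: circle, ellipse, reconstruction properties", {
  d <- efaFit(outlinePoints(circleOutline(2000)), 8)
  H <- efHarmonics(d)
  # harmonic "size" = semi-major axis of the harmonic ellipse
  amp <- apply(H, 1, function(h) svd(matrix(h, 2, 2, byrow = TRUE))$d[1])
  expect_equal(amp[1], 1, tolerance = 1e-4)
  expect_true(all(amp[-1] < 1e-6))
  # ellipse (2, 1): the full descriptor reproduces the 2:1 axis ratio (the
  # first harmonic alone under-represents eccentricity because chord-length
  # parameterization spreads it into higher harmonics -- checked against
  # the exact-integration oracle above)
  de <- efaFit(outlinePoints(ellipseOutline(2, 1, 3000)), 25)
  rt <- descriptiveTraits(efaReconstruct(de, 2000))
  expect_equal(unname(rt["LI"]), 2, tolerance = 1e-3)
  h1 <- matrix(efHarmonics(de)[1, ], 2, 2, byrow = TRUE)
  sv <- svd(h1)$d
  svo <- svd(matrix(efaOracle(outlinePoints(ellipseOutline(2, 1, 3000)),
                              2)[1, ], 2, 2, byrow = TRUE))$d
  expect_equal(sv[1] / sv[2], svo[1] / svo[2], tolerance = 1e-8)
  # reconstruction error non-increasing in harmonics
  tr <- simulateOutlines(data.frame(tree_id = "t", leaf_type = "unassigned",
                                    LI = 2))[[1]]
  p <- .resampleOracle(outlinePoints(tr), 200)
  dfit <- efaFit(p, 30)
  errs <- vapply(c(1, 2, 5, 10, 20, 30), function(nh) {
    rec <- outlinePoints(efaReconstruct(dfit, 400, nHarmonics = nh))
    sqrt(mean(apply(p, 1, function(q) min(colSums((t(rec) - q)^2)))))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
  # dc-only reconstruction collapses to the centroid
  d0 <- dfit; d0@harmonics[] <- 0
  rec0 <- outlinePoints(efaReconstruct(d0, 10))
  expect_true(all(abs(sweep(rec0, 2, dfit@dcTerms)) < 1e-10))
  # linearity: doubling the coefficients doubles the curve about centroid
  d2 <- dfit; d2@harmonics <- 2 * d2@harmonics
  r1 <- sweep(outlinePoints(efaReconstruct(dfit, 100)), 2, dfit@dcTerms)
  r2 <- sweep(outlinePoints(efaReconstruct(d2, 100)), 2, d2@dcTerms)
  expect_equal(r2, 2 * r1, tolerance = 1e-10)
  expect_error(efaFit(outlinePoints(circleOutline(10)), 25), "points")
})

test_that("descriptive traits and the leaf-index classifier agree with geometry", {
  tt <- descriptiveTraits(ellipseOutline(2, 1, 600, angle = 0.6))
  expect_equal(unname(tt["LL"]), 4, tolerance = 0.01)
  expect_equal(unname(tt["LW"]), 2, tolerance = 0.01)
  expect_equal(unname(tt["LI"]), 2, tolerance = 0.01)
  expect_equal(unname(tt["LA"]), 2 * pi, tolerance = 0.02 * 2 * pi)
  # unit square rotated 45 degrees
  sq <- LeafOutline(matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
                    %*% matrix(c(cos(pi/4), sin(pi/4),
                                 -sin(pi/4), cos(pi/4)), 2))
  ts <- descriptiveTraits(sq)
  expect_equal(unname(ts["LL"]), sqrt(2), tolerance = 1e-6)
  expect_equal(unname(ts["LW"]), sqrt(2), tolerance = 1e-6)
  expect_equal(unname(ts["LA"]), 1, tolerance = 1e-6)
  # classifier: exactly one label for any positive LI, boundaries honored
  expect_equal(classifyLeaf(c(4, 1, 0.5, 2, 3.999)),
               c("linear", "ovoid", "broad-ovate", "lanceolate",
                 "lanceolate"))
  lis <- exp(runif(500, log(0.01), log(50)))
  expect_true(all(classifyLeaf(lis) %in%
                  c("linear", "lanceolate", "ovoid", "broad-ovate")))
  expect_error(classifyLeaf(0), "positive")
})

test_that("shape PCA retains components by cumulative variance", {
  set.seed(6)
  base <- radialSemilandmarks(circleOutline(400), L = 40)
  dir <- matrix(rnorm(80), 40, 2); dir <- dir / sqrt(sum(dir^2))
  shapes <- lapply(rnorm(20), function(s) unclass(base) + s * 0.05 * dir)
  al <- procrustesNormalize(shapes)
  pc <- shapePca(al, cumThreshold = 0.96)
  expect_equal(ncol(shapeScores(pc)), 1)
  expect_gt(explainedVariance(pc)[1], 0.95)
  expect_true(all(diff(explainedVariance(pc)) <= 1e-12))
  # scores are centered: the mean configuration sits at the origin
  expect_true(all(abs(colMeans(shapeScores(pc))) < 1e-10))
  expect_error(shapePca(al[1]), "at least 2")
})

test_that("Box-Cox transform finds the right exponent", {
  set.seed(7)
  x <- rnorm(500, mean = 50, sd = 2)
  b1 <- boxcoxTransform(x)
  expect_gt(abs(cor(b1$values, x)), 0.999)  # lambda ~ 1 is affine
  y <- exp(rnorm(5000))
  b0 <- boxcoxTransform(y)
  expect_lt(abs(b0$lambda), 0.1)
  expect_gte(shapiro.test(sample(b0$values, 1000))$p.value,
             shapiro.test(sample(y, 1000))$p.value)
  expect_error(boxcoxTransform(rep(3, 10)), "constant")
})

test_that("phenotype statistics: ANOVA power, CV invariance, MANOVA", {
  set.seed(8)
  tr <- data.frame(leaf_type = rep(c("linear", "lanceolate", "ovoid",
                                     "broad-ovate"), each = 50),
                   LL = rnorm(200, 10), LW = rnorm(200, 5),
                   LI = rnorm(200, 2), LA = rnorm(200, 30))
  tr$LL[tr$leaf_type == "linear"] <- tr$LL[tr$leaf_type == "linear"] + 10
  ef <- matrix(rnorm(200 * 6), 200, 6)
  ef[tr$leaf_type == "linear", 1] <- ef[tr$leaf_type == "linear", 1] + 3
  st <- phenotypeStats(tr, efCoefs = ef)
  expect_lt(st$anova$p[st$anova$trait == "LL"], 1e-6)
  expect_true("Wilks" %in% colnames(st$manova))
  expect_lt(st$manova["grp", "Pr(>F)"], 1e-6)
  # CV scale invariance
  tr2 <- tr; tr2$LL <- tr2$LL * 7
  st2 <- phenotypeStats(tr2)
  cv1 <- st$descriptives$cv[st$descriptives$trait == "LL"]
  cv2 <- st2$descriptives$cv[st2$descriptives$trait == "LL"]
  expect_equal(cv1, cv2, tolerance = 1e-12)
  # degenerate zero-variance groups are flagged
  tr3 <- tr; tr3$LL <- 1
  expect_true(phenotypeStats(tr3)$anova$degenerate[1])
  expect_error(phenotypeStats(tr[c(1, 51, 101, 151, 2), ]), ">= 2")
})
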