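# Shared fixture builders (all generated in code; no stored data).

circleOutline <- function(n = 200, r = 1, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  LeafOutline(cbind(cx + r * cos(th), cy + r * sin(th)))
}

ellipseOutline <- function(a = 2, b = 1, n = 200, angle = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  p <- cbind(a * cos(th), b * sin(th))
  if (angle != 0) {
    R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
    p <- p %*% t(R)
  }
  LeafOutline(p)
}

# small GenotypeData from an explicit call matrix
toyGenotypes <- function(calls, pos = NULL, chrom = "chr1") {
  m <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  GenotypeData(calls, data.frame(chrom = chrom, pos = pos,
                                 ref = "A", alt = "T", mq = 60, depth = 50))
}

# equal-arc-length closed resampling for test geometry
.resampleOracle <- function(p, n) {
  pc <- rbind(p, p[1, ])
  t <- c(0, cumsum(sqrt(rowSums(diff(pc)^2))))
  tt <- seq(0, t[length(t)], length.out = n + 1)[-(n + 1)]
  cbind(approx(t, pc[, 1], xout = tt)$y, approx(t, pc[, 2], xout = tt)$y)
}

# shoelace area (independent of the package's internal helper)
.hg_area <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1)
  sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]) / 2
}

# independent brute-force MVN log-likelihood with an explicit covariance
mvnLogLik <- function(Y, mu, Sigma) {
  n <- nrow(Y)
  R <- sweep(Y, 2, mu)
  ld <- determinant(Sigma, logarithm = TRUE)$modulus[1]
  Si <- solve(Sigma)
  -n * ncol(Y) / 2 * log(2 * pi) - n / 2 * ld - 0.5 * sum((R %*% Si) * R)
}

# independent SAD(1) covariance from the recursion, element by element
sadCovBrute <- function(phi, nu2, T = 4) {
  S <- matrix(0, T, T)
  for (t in 1:T) for (s in 1:T) {
    mn <- min(t, s)
    S[t, s] <- nu2 * phi^(abs(t - s)) *
      sum(phi^(2 * (mn - seq_len(mn))))
  }
  S
}
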