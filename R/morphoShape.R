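# Shape-side morphometrics: radial semi-landmarks, generalized Procrustes
# alignment, elliptic Fourier analysis, descriptive traits and the
# phenotype-level statistics.

# ---- polygon helpers -------------------------------------------------------

# equal-arc-length resampling of a closed polygon (first vertex not repeated)
.resampleClosed <- function(p, n) {
  pc <- rbind(p, p[1, ])
  seg <- sqrt(rowSums(diff(pc)^2))
  t <- c(0, cumsum(seg))
  tt <- seq(0, t[length(t)], length.out = n + 1)[-(n + 1)]
  cbind(approx(t, pc[, 1], xout = tt)$y, approx(t, pc[, 2], xout = tt)$y)
}

# area centroid of a simple polygon
.polyCentroid <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1)
  cr <- p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]
  A <- sum(cr) / 2
  if (abs(A) < 1e-12) return(colMeans(p))
  c(sum((p[, 1] + p[i2, 1]) * cr), sum((p[, 2] + p[i2, 2]) * cr)) / (6 * A)
}

# distances from `center` to the boundary along rays at `angles`;
# farthest intersection is taken, and rays hitting the boundary more than
# once are counted (star-shape violation diagnostics)
.radialRadii <- function(p, center, angles) {
  n <- nrow(p)
  i2 <- c(2:n, 1)
  ax <- p[, 1] - center[1]; ay <- p[, 2] - center[2]
  bx <- p[i2, 1] - center[1]; by <- p[i2, 2] - center[2]
  ex <- bx - ax; ey <- by - ay
  radii <- numeric(length(angles))
  hits <- integer(length(angles))
  for (k in seq_along(angles)) {
    dx <- cos(angles[k]); dy <- sin(angles[k])
    den <- dx * ey - dy * ex
    ok <- abs(den) > 1e-14
    u <- (ax * ey - ay * ex) / den        # distance along ray
    v <- (ax * dy - ay * dx) / den        # position within edge [0,1)
    good <- ok & u > 0 & v >= 0 & v < 1
    s <- u[good]
    hits[k] <- length(s)
    radii[k] <- if (length(s)) max(s) else NA_real_
  }
  list(radii = radii, hits = hits)
}

# Midrib (base->tip) axis of a leaf outline. Principal axes are computed
# from the arc-length-resampled boundary; between the two principal axes
# the midrib is the one with the smaller reflection asymmetry of the radial
# function, with the major axis as tie-break (a leaf is bilaterally
# symmetric about its midrib but tapers along it; an ellipse keeps its
# major axis). `tip` points from base to tip (the narrower half).
.leafAxes <- function(p, nResample = 360L) {
  q <- .resampleClosed(p, nResample)
  ctr <- .polyCentroid(p)
  qc <- sweep(q, 2, ctr)
  ev <- eigen(crossprod(qc) / nrow(qc), symmetric = TRUE)
  ax1 <- ev$vectors[, 1]; ax2 <- ev$vectors[, 2]
  # isotropic boundary (circle, square): principal axes are arbitrary, so
  # fall back to the coordinate axes for reproducible measurements
  if (ev$values[1] - ev$values[2] < 1e-6 * ev$values[1]) {
    ax1 <- c(1, 0); ax2 <- c(0, 1)
  }
  asym <- function(u) {
    th0 <- atan2(u[2], u[1])
    dth <- seq(0.05, pi - 0.05, length.out = 60)
    rr <- .radialRadii(p, ctr, c(th0 + dth, th0 - dth))
    r <- rr$radii
    a <- r[seq_along(dth)]; b <- r[seq_along(dth) + length(dth)]
    ok <- is.finite(a) & is.finite(b)
    sum(abs(a[ok] - b[ok])) / sum(a[ok] + b[ok])
  }
  a1 <- asym(ax1); a2 <- asym(ax2)
  axis <- if (a2 < 0.5 * a1 && a1 > 0.02) ax2 else ax1
  perp <- c(-axis[2], axis[1])
  proj <- qc %*% axis
  wAbs <- abs(qc %*% perp)
  mid <- median(proj)
  # the tip half has the smaller mean half-width
  tipPos <- mean(wAbs[proj > mid]) < mean(wAbs[proj <= mid])
  if (!tipPos) axis <- -axis
  list(center = ctr, axis = axis, perp = c(-axis[2], axis[1]),
       asym = c(a1, a2))
}

# ---- semi-landmarks and alignment -----------------------------------------

#' Radial semi-landmarks at equal angles around the centroid
#'
#' Places L boundary points at angles 2*pi*k/L (k = 0..L-1, clockwise) from
#' the area centroid, starting on the base-to-tip (midrib) axis, with linear
#' interpolation along polygon edges. If a ray meets the boundary more than
#' once (the outline is not star-shaped about its centroid) the farthest
#' intersection is used and the result is flagged.
#'
#' @param outline a \linkS4class{LeafOutline}.
#' @param L number of semi-landmarks (default 100).
#' @return L x 2 matrix of absolute coordinates with attributes
#'   \code{startAngle} (radians), \code{center}, and \code{flagged}
#'   (TRUE if the star-shape assumption was violated).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 201)[-201]
#' circ <- LeafOutline(cbind(cos(th), sin(th)))
#' sl <- radialSemilandmarks(circ, L = 16)
#' range(sqrt(rowSums(sl^2)))  # all radii 1
#' @export
radialSemilandmarks <- function(outline, L = 100L) {
  p <- outlinePoints(outline)
  ax <- .leafAxes(p)
  th0 <- atan2(ax$axis[2], ax$axis[1])
  angles <- th0 - 2 * pi * (seq_len(L) - 1) / L
  rr <- .radialRadii(p, ax$center, angles)
  if (anyNA(rr$radii))
    stop("centroid ray found no boundary intersection; degenerate outline")
  out <- cbind(x = ax$center[1] + rr$radii * cos(angles),
               y = ax$center[2] + rr$radii * sin(angles))
  attr(out, "startAngle") <- th0
  attr(out, "center") <- ax$center
  attr(out, "flagged") <- any(rr$hits > 1)
  out
}

.centroidSize <- function(x) sqrt(sum(sweep(x, 2, colMeans(x))^2))

#' Generalized Procrustes alignment of semi-landmark sets
#'
#' Centers every configuration at the origin, scales it to unit centroid
#' size, and rotates it by orthogonal (rotation-only) Procrustes onto the
#' iteratively re-estimated mean shape until the mean changes by less than
#' \code{tol}.
#'
#' @param shapes list of L x 2 matrices sharing the same L.
#' @param tol convergence tolerance on the mean shape (default 1e-8).
#' @param maxIter iteration cap (default 100).
#' @return list of aligned L x 2 matrices, with the consensus in
#'   \code{attr(, "meanShape")} and the iteration count in
#'   \code{attr(, "iterations")}.
#' @export
procrustesNormalize <- function(shapes, tol = 1e-8, maxIter = 100L) {
  stopifnot(is.list(shapes), length(shapes) >= 1)
  L <- nrow(shapes[[1]])
  if (!all(vapply(shapes, nrow, 1L) == L))
    stop("all shapes must share the same number of landmarks")
  norm1 <- function(x) {
    x <- sweep(x, 2, colMeans(x))
    cs <- sqrt(sum(x^2))
    if (cs < 1e-12) stop("degenerate shape: zero centroid size")
    x / cs
  }
  shapes <- lapply(shapes, norm1)
  rotTo <- function(x, ref) {
    s <- svd(crossprod(x, ref))
    R <- s$u %*% t(s$v)
    if (det(R) < 0) {             # rotation only, no reflection
      s$v[, 2] <- -s$v[, 2]
      R <- s$u %*% t(s$v)
    }
    x %*% R
  }
  mn <- shapes[[1]]
  iter <- 0L
  repeat {
    iter <- iter + 1L
    shapes <- lapply(shapes, rotTo, ref = mn)
    newMn <- norm1(Reduce(`+`, shapes) / length(shapes))
    delta <- sqrt(sum((newMn - mn)^2))
    mn <- newMn
    if (delta < tol || iter >= maxIter) break
  }
  attr(shapes, "meanShape") <- mn
  attr(shapes, "iterations") <- iter
  shapes
}

# ---- elliptic Fourier analysis --------------------------------------------

#' Elliptic Fourier descriptor of a closed contour
#'
#' Kuhl-Giardina elliptic Fourier coefficients under chord-length
#' parameterization, computed in closed form for the piecewise-linear
#' contour. The DC terms are the arc-length centroid of the curve.
#'
#' @param points closed contour: an n x 2 matrix (first vertex not
#'   repeated) or a \linkS4class{LeafOutline}.
#' @param nHarmonics number of harmonics (default 25).
#' @return an \linkS4class{EFDescriptor}.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 500)[-500]
#' d <- efaFit(cbind(2 * cos(th), sin(th)), nHarmonics = 10)
#' efHarmonics(d)[1, ]  # first-harmonic quadruple of a 2:1 ellipse
#' @export
efaFit <- function(points, nHarmonics = 25L) {
  if (is(points, "LeafOutline")) points <- outlinePoints(points)
  p <- as.matrix(points)
  n <- nrow(p)
  if (n < 2 * nHarmonics + 1)
    stop("need at least 2*nHarmonics + 1 points (got ", n, ")")
  i2 <- c(2:n, 1)
  dx <- p[i2, 1] - p[, 1]
  dy <- p[i2, 2] - p[, 2]
  dt <- sqrt(dx^2 + dy^2)
  if (any(dt == 0)) {
    keep <- dt > 0
    return(efaFit(p[keep, , drop = FALSE], nHarmonics))
  }
  t1 <- cumsum(dt)
  t0 <- c(0, t1[-n])
  T <- t1[n]
  H <- matrix(0, nHarmonics, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  for (h in seq_len(nHarmonics)) {
    w <- 2 * pi * h / T
    dcos <- cos(w * t1) - cos(w * t0)
    dsin <- sin(w * t1) - sin(w * t0)
    k <- T / (2 * pi^2 * h^2)
    H[h, ] <- k * c(sum(dx / dt * dcos), sum(dx / dt * dsin),
                    sum(dy / dt * dcos), sum(dy / dt * dsin))
  }
  dc <- c(sum(dt * (p[, 1] + p[i2, 1]) / 2),
          sum(dt * (p[, 2] + p[i2, 2]) / 2)) / T
  new("EFDescriptor", harmonics = H, dcTerms = dc)
}

#' Reconstruct a contour from elliptic Fourier coefficients
#'
#' @param d an \linkS4class{EFDescriptor}.
#' @param nPoints number of points to sample (default 300).
#' @param nHarmonics harmonics to use (default: all in \code{d}).
#' @return a \linkS4class{LeafOutline}.
#' @export
efaReconstruct <- function(d, nPoints = 300L, nHarmonics = NULL) {
  H <- d@harmonics
  if (!is.null(nHarmonics)) H <- H[seq_len(nHarmonics), , drop = FALSE]
  u <- seq(0, 2 * pi, length.out = nPoints + 1)[-(nPoints + 1)]
  x <- rep(d@dcTerms[1], nPoints)
  y <- rep(d@dcTerms[2], nPoints)
  for (h in seq_len(nrow(H))) {
    x <- x + H[h, "a"] * cos(h * u) + H[h, "b"] * sin(h * u)
    y <- y + H[h, "c"] * cos(h * u) + H[h, "d"] * sin(h * u)
  }
  LeafOutline(cbind(x, y))
}

# ---- descriptive traits ----------------------------------------------------

#' Descriptive leaf traits: length, width, index, area
#'
#' LL is the extent of the outline along its base-to-tip (midrib) axis, LW
#' the maximal extent perpendicular to it, LI = LL/LW, and LA the shoelace
#' polygon area. The midrib is chosen between the two principal axes by
#' bilateral symmetry (see \code{\link{radialSemilandmarks}}), so
#' broad-ovate leaves (wider than long) correctly report LI < 1. Units
#' follow \code{pixelScale} when set.
#'
#' @param outline a \linkS4class{LeafOutline}.
#' @return named numeric: \code{LL}, \code{LW}, \code{LI}, \code{LA}.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 400)[-400]
#' descriptiveTraits(LeafOutline(cbind(2 * cos(th), sin(th))))
#' @export
descriptiveTraits <- function(outline) {
  p <- outlinePoints(outline)
  ax <- .leafAxes(p)
  # extents from the vertices themselves (resampling can clip extrema)
  pc <- sweep(p, 2, ax$center)
  LL <- diff(range(pc %*% ax$axis))
  LW <- diff(range(pc %*% ax$perp))
  if (LL <= 0 || LW <= 0) stop("degenerate outline")
  sc <- outline@pixelScale
  if (is.na(sc)) sc <- 1
  c(LL = LL * sc, LW = LW * sc, LI = LL / LW,
    LA = abs(.signedArea(p)) * sc^2)
}

#' Classify a leaf by its leaf index
#'
#' Four classes on half-open intervals of LI = LL/LW: linear (LI >= 4),
#' lanceolate (4 > LI >= 2), ovoid (2 > LI >= 1), broad-ovate (LI < 1).
#'
#' @param LI positive leaf index (vectorized).
#' @param eps boundary tolerance absorbing floating-point noise in measured
#'   ratios (default 1e-9).
#' @return character vector of class labels.
#' @examples
#' classifyLeaf(c(0.5, 1, 2, 4, 6))
#' @export
classifyLeaf <- function(LI, eps = 1e-9) {
  if (any(!is.finite(LI) | LI <= 0)) stop("LI must be positive")
  # eps absorbs floating-point noise in measured ratios at the boundaries
  ifelse(LI >= 4 - eps, "linear",
         ifelse(LI >= 2 - eps, "lanceolate",
                ifelse(LI >= 1 - eps, "ovoid", "broad-ovate")))
}

# ---- outline CSV interchange ----------------------------------------------

#' Read leaf outlines from a long-format CSV
#'
#' Expects columns \code{tree_id}, \code{leaf_type}, \code{point_index},
#' \code{x}, \code{y}; one \linkS4class{LeafOutline} is built per
#' (tree_id, leaf_type) with points ordered by \code{point_index}.
#'
#' @param path CSV file.
#' @return list of \linkS4class{LeafOutline} objects.
#' @export
readOutlinesCsv <- function(path) {
  d <- read.csv(path)
  need <- c("tree_id", "leaf_type", "point_index", "x", "y")
  if (!all(need %in% colnames(d)))
    stop("outline CSV needs columns: ", paste(need, collapse = ", "))
  unname(lapply(split(d, paste(d$tree_id, d$leaf_type, sep = "\r")),
                function(s) {
    s <- s[order(s$point_index), ]
    LeafOutline(cbind(s$x, s$y), treeId = as.character(s$tree_id[1]),
                leafType = as.character(s$leaf_type[1]))
  }))
}

#' Write leaf outlines to a long-format CSV
#' @param outlines list of \linkS4class{LeafOutline} objects.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeOutlinesCsv <- function(outlines, path) {
  d <- do.call(rbind, lapply(outlines, function(o) {
    p <- outlinePoints(o)
    data.frame(tree_id = treeId(o), leaf_type = leafType(o),
               point_index = seq_len(nrow(p)), x = p[, 1], y = p[, 2])
  }))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

# ---- shape PCA and trait statistics ---------------------------------------

#' PCA of aligned semi-landmark coordinates
#'
#' Flattens each aligned L x 2 configuration to a 2L vector (x then y),
#' performs covariance PCA, and retains the smallest number of components
#' whose cumulative explained variance exceeds \code{cumThreshold}.
#'
#' @param aligned list of aligned L x 2 matrices (from
#'   \code{\link{procrustesNormalize}}).
#' @param cumThreshold cumulative-variance retention threshold
#'   (default 0.96).
#' @return a \linkS4class{ShapePCA}.
#' @export
shapePca <- function(aligned, cumThreshold = 0.96) {
  if (length(aligned) < 2) stop("need at least 2 shapes")
  X <- t(vapply(aligned, function(s) c(s[, 1], s[, 2]),
                numeric(2 * nrow(aligned[[1]]))))
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(frac) > cumThreshold)[1]
  if (is.na(k)) k <- length(frac)
  new("ShapePCA", meanShape = pc$center,
      loadings = pc$rotation[, seq_len(k), drop = FALSE],
      explained = frac[seq_len(k)],
      scores = pc$x[, seq_len(k), drop = FALSE],
      cumThreshold = cumThreshold)
}

#' Box-Cox normalization with profile-likelihood lambda
#'
#' Shifts the data to be strictly positive if necessary (shift recorded),
#' chooses lambda on [-5, 5] by profile maximum likelihood, and returns the
#' transformed values.
#'
#' @param values numeric vector.
#' @param lambdaRange search interval (default c(-5, 5)).
#' @return list with \code{values} (transformed), \code{lambda},
#'   \code{shift}.
#' @export
boxcoxTransform <- function(values, lambdaRange = c(-5, 5)) {
  if (sd(values) == 0) stop("constant input")
  shift <- 0
  if (min(values) <= 0)
    shift <- -min(values) + 1e-3 * diff(range(values))
  x <- values + shift
  prof <- function(lam) {
    y <- if (abs(lam) < 1e-8) log(x) else (x^lam - 1) / lam
    -length(x) / 2 * log(mean((y - mean(y))^2)) + (lam - 1) * sum(log(x))
  }
  opt <- optimize(prof, lambdaRange, maximum = TRUE)
  lam <- opt$maximum
  y <- if (abs(lam) < 1e-8) log(x) else (x^lam - 1) / lam
  list(values = y, lambda = lam, shift = shift)
}

#' Phenotype-level statistics across the four leaf types
#'
#' Per trait and leaf type: mean, SD, CV, skewness, kurtosis and
#' Shapiro-Wilk normality p; per trait: one-way ANOVA across leaf types
#' and Bonferroni-adjusted pairwise comparisons; a Spearman correlation
#' matrix across traits; and, when elliptic Fourier coefficients are
#' supplied, a MANOVA (Wilks' lambda with F approximation) testing outline
#' differences among leaf types.
#'
#' @param traits data.frame with a \code{leaf_type} column and numeric
#'   trait columns.
#' @param traitCols names of the trait columns (default LL, LW, LI, LA).
#' @param efCoefs optional matrix of per-leaf EF coefficients (rows aligned
#'   with \code{traits}) for the MANOVA.
#' @return list with \code{descriptives}, \code{anova}, \code{pairwise},
#'   \code{spearman}, and (if requested) \code{manova}.
#' @export
phenotypeStats <- function(traits, traitCols = c("LL", "LW", "LI", "LA"),
                           efCoefs = NULL) {
  stopifnot("leaf_type" %in% colnames(traits))
  grp <- factor(traits$leaf_type)
  if (any(table(grp) < 2)) stop("every leaf type needs >= 2 observations")
  traitCols <- intersect(traitCols, colnames(traits))
  desc <- do.call(rbind, lapply(traitCols, function(tc) {
    do.call(rbind, lapply(levels(grp), function(g) {
      v <- traits[grp == g, tc]
      sw <- if (length(v) >= 3 && sd(v) > 0)
        shapiro.test(v)$p.value else NA_real_
      data.frame(trait = tc, leaf_type = g, n = length(v),
                 mean = mean(v), sd = sd(v),
                 cv = sd(v) / abs(mean(v)),
                 skewness = e1071::skewness(v),
                 kurtosis = e1071::kurtosis(v) + 3,
                 shapiro_p = sw)
    }))
  }))
  anv <- do.call(rbind, lapply(traitCols, function(tc) {
    v <- traits[[tc]]
    if (all(tapply(v, grp, sd) == 0))
      return(data.frame(trait = tc, F = NA_real_, p = NA_real_,
                        degenerate = TRUE))
    a <- summary(aov(v ~ grp))[[1]]
    data.frame(trait = tc, F = a$`F value`[1], p = a$`Pr(>F)`[1],
               degenerate = FALSE)
  }))
  pw <- lapply(setNames(traitCols, traitCols), function(tc)
    pairwise.t.test(traits[[tc]], grp, p.adjust.method = "bonferroni")$p.value)
  sp <- suppressWarnings(cor(traits[, traitCols, drop = FALSE],
                             method = "spearman"))
  out <- list(descriptives = desc, anova = anv, pairwise = pw, spearman = sp)
  if (!is.null(efCoefs)) {
    fit <- manova(as.matrix(efCoefs) ~ grp)
    out$manova <- summary(fit, test = "Wilks")$stats
  }
  out
}
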