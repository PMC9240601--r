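# Image-side morphometrics: red-background segmentation and sub-pixel
# outline tracing. Images are plain R arrays [row, col, channel] with values
# in [0, 1] (as returned by png::readPNG); rows run top to bottom, so the
# outline coordinate frame is x = column, y = row (y-down).

#' Segment a leaf from a red-background photograph
#'
#' A pixel is background iff R - max(G, B) > \code{redMargin} (on the 8-bit
#' scale; the default 40 separates a saturated red backdrop from green/brown
#' leaf tissue). The largest connected foreground component is retained and
#' its holes filled.
#'
#' @param image numeric array h x w x 3 in [0, 1] (values in [0, 255] are
#'   rescaled), or a path to a PNG file.
#' @param redMargin 8-bit red-dominance threshold for background (default 40).
#' @param minArea minimum foreground component size in pixels (default 50).
#' @return logical matrix h x w; TRUE = leaf.
#' @examples
#' out <- simulateOutlines(data.frame(tree_id = "t1", leaf_type = "ovoid",
#'                                    LI = 1.5))[[1]]
#' img <- rasterizeOutline(out, size = 128)
#' mask <- segmentLeaf(img)
#' sum(mask) > 0
#' @export
segmentLeaf <- function(image, redMargin = 40, minArea = 50) {
  if (is.character(image)) image <- png::readPNG(image)
  if (length(dim(image)) == 3 && dim(image)[3] >= 3)
    image <- image[, , 1:3]
  else stop("need an RGB image (h x w x 3 array)")
  if (max(image) > 1.5) image <- image / 255
  bg <- image[, , 1] - pmax(image[, , 2], image[, , 3]) > redMargin / 255
  fg <- !bg
  lab <- EBImage::bwlabel(fg)
  sizes <- tabulate(lab[lab > 0])
  if (!length(sizes) || max(sizes) < minArea)
    stop("segmentation error: no foreground component with >= ", minArea,
         " pixels")
  mask <- lab == which.max(sizes)
  mask <- EBImage::fillHull(EBImage::Image(mask)) > 0
  matrix(as.logical(mask), nrow(fg), ncol(fg))
}

#' Trace the outline of a binary mask at sub-pixel resolution
#'
#' Extracts the 0.5 level set of the mask by linear interpolation
#' (\code{grDevices::contourLines}), then applies Taubin lambda/mu contour
#' smoothing -- a low-pass filter designed to suppress the pixel-quantization
#' staircase without shrinking the shape -- giving an ordered, closed,
#' sub-pixel boundary polygon stored clockwise.
#'
#' @param mask logical or 0/1 matrix with exactly one foreground component.
#' @param smoothIter Taubin smoothing iterations (default 10; 0 disables
#'   smoothing and returns the raw marching-squares polygon).
#' @param treeId,leafType,pixelScale passed through to the
#'   \linkS4class{LeafOutline}.
#' @return a \linkS4class{LeafOutline} in (x = column, y = row) pixel
#'   coordinates.
#' @export
traceOutline <- function(mask, treeId = NA_character_,
                         leafType = "unassigned", pixelScale = NA_real_,
                         smoothIter = 10L) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m > 0)
  ncomp <- max(lab)
  if (ncomp != 1)
    stop("mask must contain exactly one component (found ", ncomp, ")")
  # pad so boundary-touching components still produce closed contours
  mp <- matrix(0, nrow(m) + 4, ncol(m) + 4)
  mp[3:(nrow(m) + 2), 3:(ncol(m) + 2)] <- m
  cl <- contourLines(x = seq_len(nrow(mp)), y = seq_len(ncol(mp)),
                     z = mp, levels = 0.5)
  if (!length(cl)) stop("no contour found")
  # outer boundary = contour with the largest absolute enclosed area
  areas <- vapply(cl, function(cc) {
    p <- cbind(cc$x, cc$y)
    abs(.signedArea(p[-nrow(p), , drop = FALSE]))
  }, numeric(1))
  cc <- cl[[which.max(areas)]]
  # contourLines used x = rows, y = cols; convert to x = col, y = row and
  # undo the 2-pixel pad
  pts <- cbind(x = cc$y - 2, y = cc$x - 2)
  if (nrow(pts) > 2 &&
      all(abs(pts[1, ] - pts[nrow(pts), ]) < 1e-12))
    pts <- pts[-nrow(pts), , drop = FALSE]
  if (smoothIter > 0) pts <- .taubinSmooth(pts, iter = smoothIter)
  LeafOutline(pts, treeId = treeId, leafType = leafType,
              pixelScale = pixelScale)
}

# Taubin lambda|mu smoothing of a closed polygon: alternating shrink/inflate
# umbrella steps low-pass the boundary with negligible net area change.
.taubinSmooth <- function(p, lambda = 0.5, mu = -0.53, iter = 10L) {
  n <- nrow(p)
  if (n < 5) return(p)
  up <- function(q) 0.5 * (q[c(2:n, 1), , drop = FALSE] +
                           q[c(n, 1:(n - 1)), , drop = FALSE]) - q
  for (i in seq_len(iter)) {
    p <- p + lambda * up(p)
    p <- p + mu * up(p)
  }
  p
}

#' Rasterize a leaf outline onto a red background
#'
#' Renders the polygon as a filled green leaf on the configured red backdrop
#' (default RGB 200, 30, 30), scaled to occupy \code{fill} of the frame;
#' used to exercise the full image pipeline on synthetic leaves.
#'
#' @param outline a \linkS4class{LeafOutline}.
#' @param size image side in pixels (default 512).
#' @param fill fraction of the frame spanned by the leaf's larger extent
#'   (default 0.7).
#' @param bg,fgCol background / leaf RGB triplets in [0, 1].
#' @param binary if TRUE return a logical mask instead of an RGB array.
#' @return h x w x 3 numeric array in [0, 1], or a logical matrix.
#' @export
rasterizeOutline <- function(outline, size = 512L, fill = 0.7,
                             bg = c(200, 30, 30) / 255,
                             fgCol = c(60, 140, 50) / 255, binary = FALSE) {
  p <- outlinePoints(outline)
  rng <- apply(p, 2, range)
  span <- max(rng[2, ] - rng[1, ])
  sc <- fill * size / span
  ctr <- colMeans(rng)
  q <- sweep(p, 2, ctr) * sc
  q <- sweep(q, 2, c(size / 2, size / 2), "+")
  mask <- .fillPolygon(q, size, size)
  if (binary) return(mask)
  img <- array(rep(bg, each = size * size), dim = c(size, size, 3))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- fgCol[ch]
    img[, , ch] <- plane
  }
  img
}

# Even-odd scanline fill; polygon in (x = col, y = row) continuous
# coordinates, pixel centers at integers.
.fillPolygon <- function(p, nrow, ncol) {
  mask <- matrix(FALSE, nrow, ncol)
  n <- nrow(p)
  x <- p[, 1]; y <- p[, 2]
  x2 <- x[c(2:n, 1)]; y2 <- y[c(2:n, 1)]
  for (r in seq_len(nrow)) {
    yr <- r
    crosses <- ((y <= yr) & (y2 > yr)) | ((y2 <= yr) & (y > yr))
    if (!any(crosses)) next
    xs <- x[crosses] + (yr - y[crosses]) / (y2[crosses] - y[crosses]) *
      (x2[crosses] - x[crosses])
    xs <- sort(xs)
    for (k in seq(1, length(xs) - 1, by = 2)) {
      c1 <- ceiling(xs[k]); c2 <- floor(xs[k + 1])
      if (c2 >= c1) {
        c1 <- max(1, c1); c2 <- min(ncol, c2)
        if (c2 >= c1) mask[r, c1:c2] <- TRUE
      }
    }
  }
  mask
}
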