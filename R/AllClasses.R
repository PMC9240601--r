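#' GenotypeData: individuals-by-SNPs biallelic genotype calls
#'
#' Holds additive genotype codes (0/1/2 copies of the alternate allele,
#' \code{NA} for missing) together with per-SNP metadata (chromosome,
#' 1-based position, alleles, mapping quality, mean depth).
#'
#' @slot calls numeric matrix, individuals x SNPs, values in \{0,1,2,NA\}.
#' @slot snpMeta data.frame with one row per SNP: \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, and optionally \code{mq} (mapping quality) and
#'   \code{depth} (mean depth of coverage).
#' @slot sampleIds character vector of individual identifiers.
#'
#' @examples
#' g <- simulateGenotypes(simConfig(n_individuals = 10, n_snps = 5, seed = 1))
#' dim(genotypeCalls(g))
#' head(snpMeta(g))
#' @export
setClass("GenotypeData",
  representation(calls = "matrix", snpMeta = "data.frame",
                 sampleIds = "character"))

setValidity("GenotypeData", function(object) {
  msg <- character()
  cl <- object@calls
  if (ncol(cl) != nrow(object@snpMeta))
    msg <- c(msg, "ncol(calls) must equal nrow(snpMeta)")
  if (nrow(cl) != length(object@sampleIds))
    msg <- c(msg, "nrow(calls) must equal length(sampleIds)")
  if (!all(c("chrom", "pos", "ref", "alt") %in% colnames(object@snpMeta)))
    msg <- c(msg, "snpMeta needs columns chrom, pos, ref, alt")
  v <- cl[!is.na(cl)]
  if (length(v) && !all(v %in% 0:2))
    msg <- c(msg, "calls must be 0, 1, 2 or NA (biallelic coding)")
  if (!length(msg) && nrow(object@snpMeta)) {
    bad <- vapply(split(object@snpMeta$pos, object@snpMeta$chrom),
                  function(p) any(diff(p) <= 0), logical(1))
    if (any(bad))
      msg <- c(msg, "pos must be strictly increasing within each chrom")
  }
  if (length(msg)) msg else TRUE
})

#' KinshipMatrix: pairwise relatedness among individuals
#'
#' @slot values symmetric numeric matrix, individuals x individuals.
#' @slot estimator character tag, \code{"grm"} (realized relationship matrix,
#'   positive semi-definite, usable as the mixed-model covariance) or
#'   \code{"king"} (KING-robust, QC only; may be negative).
#' @export
setClass("KinshipMatrix",
  representation(values = "matrix", estimator = "character"))

setValidity("KinshipMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  if (max(abs(v - t(v))) > 1e-8) return("values must be symmetric")
  if (!object@estimator %in% c("grm", "king"))
    return("estimator must be 'grm' or 'king'")
  TRUE
})

#' LeafOutline: closed two-dimensional leaf contour
#'
#' The polygon is stored without repeating the first vertex; closure is
#' implicit. Winding is clockwise in a y-down (image) coordinate sense,
#' i.e. negative shoelace signed area.
#'
#' @slot points numeric matrix (n x 2) of x,y vertices, n >= 3.
#' @slot treeId character identifier of the source tree.
#' @slot leafType one of \code{"linear"}, \code{"lanceolate"},
#'   \code{"ovoid"}, \code{"broad-ovate"} or \code{"unassigned"}.
#' @slot pixelScale length units per pixel (NA_real_ if unknown).
#' @slot flags character vector of quality flags (e.g. a star-shape
#'   violation during radial sampling).
#' @export
setClass("LeafOutline",
  representation(points = "matrix", treeId = "character",
                 leafType = "character", pixelScale = "numeric",
                 flags = "character"),
  prototype(treeId = NA_character_, leafType = "unassigned",
            pixelScale = NA_real_, flags = character()))

setValidity("LeafOutline", function(object) {
  p <- object@points
  if (ncol(p) != 2) return("points must be an n x 2 matrix")
  if (nrow(p) < 3) return("an outline needs at least 3 points")
  if (any(!is.finite(p))) return("points must be finite")
  ok <- c("linear", "lanceolate", "ovoid", "broad-ovate", "unassigned")
  if (!object@leafType %in% ok)
    return(paste("leafType must be one of:", paste(ok, collapse = ", ")))
  TRUE
})

#' EFDescriptor: elliptic Fourier coefficients of a closed contour
#'
#' @slot harmonics numeric matrix (n_harmonics x 4) with columns
#'   \code{a}, \code{b}, \code{c}, \code{d} (Kuhl-Giardina quadruples).
#' @slot dcTerms length-2 numeric, the contour centroid (A0, C0).
#' @export
setClass("EFDescriptor",
  representation(harmonics = "matrix", dcTerms = "numeric"))

setValidity("EFDescriptor", function(object) {
  if (ncol(object@harmonics) != 4) return("harmonics must have 4 columns")
  if (nrow(object@harmonics) < 1) return("need at least one harmonic")
  if (length(object@dcTerms) != 2) return("dcTerms must have length 2")
  TRUE
})

#' Sad1Params: first-order structured antedependence parameters
#'
#' The SAD(1) model writes the residual at canopy position t as
#' \eqn{e_t = \phi e_{t-1} + \epsilon_t}, \eqn{\epsilon_t \sim N(0, \nu^2)},
#' with \eqn{e_0 = 0}; phi is the antedependence coefficient and nu2 the
#' innovation variance.
#'
#' @slot phi numeric antedependence coefficient (any real value).
#' @slot nu2 positive innovation variance.
#' @export
setClass("Sad1Params", representation(phi = "numeric", nu2 = "numeric"))

setValidity("Sad1Params", function(object) {
  if (length(object@phi) != 1 || length(object@nu2) != 1)
    return("phi and nu2 must be scalars")
  if (!is.finite(object@nu2) || object@nu2 <= 0) return("nu2 must be > 0")
  TRUE
})

#' ShapePCA: principal components of aligned semi-landmark coordinates
#'
#' @slot meanShape numeric vector of length 2L (the consensus configuration,
#'   interleaved as x1..xL, y1..yL).
#' @slot loadings matrix (2L x k) of orthonormal component vectors.
#' @slot explained numeric vector of per-component variance fractions,
#'   non-increasing.
#' @slot scores matrix (n_shapes x k) of shape scores.
#' @slot cumThreshold the cumulative-variance retention threshold used.
#' @export
setClass("ShapePCA",
  representation(meanShape = "numeric", loadings = "matrix",
                 explained = "numeric", scores = "matrix",
                 cumThreshold = "numeric"))

setValidity("ShapePCA", function(object) {
  e <- object@explained
  if (any(e < -1e-12 | e > 1 + 1e-12)) return("explained fractions outside [0,1]")
  if (any(diff(e) > 1e-12)) return("explained fractions must be non-increasing")
  if (sum(e) > 1 + 1e-8) return("explained fractions must sum to <= 1")
  if (ncol(object@loadings) != length(e))
    return("one explained fraction per retained component")
  TRUE
})

# ---- constructors ----------------------------------------------------------

#' Create a GenotypeData object
#'
#' @param calls individuals x SNPs matrix of 0/1/2/NA additive codes.
#' @param snpMeta per-SNP data.frame (chrom, pos, ref, alt, optionally mq,
#'   depth).
#' @param sampleIds individual identifiers; defaults to rownames of
#'   \code{calls} or \code{ind1..indN}.
#' @return a \linkS4class{GenotypeData}.
#' @export
GenotypeData <- function(calls, snpMeta, sampleIds = NULL) {
  if (is.null(sampleIds))
    sampleIds <- rownames(calls)
  if (is.null(sampleIds))
    sampleIds <- paste0("ind", seq_len(nrow(calls)))
  new("GenotypeData", calls = as.matrix(calls),
      snpMeta = as.data.frame(snpMeta), sampleIds = as.character(sampleIds))
}

#' Create a LeafOutline, enforcing clockwise winding
#'
#' @param points n x 2 matrix of vertices (first vertex not repeated).
#' @param treeId,leafType,pixelScale,flags see \linkS4class{LeafOutline}.
#' @return a \linkS4class{LeafOutline}.
#' @export
LeafOutline <- function(points, treeId = NA_character_,
                        leafType = "unassigned", pixelScale = NA_real_,
                        flags = character()) {
  points <- as.matrix(points)
  colnames(points) <- c("x", "y")
  # drop a duplicated closing vertex if the caller supplied one
  n <- nrow(points)
  if (n > 3 && all(abs(points[1, ] - points[n, ]) < 1e-12))
    points <- points[-n, , drop = FALSE]
  if (.signedArea(points) > 0) points <- points[rev(seq_len(nrow(points))), ]
  new("LeafOutline", points = points, treeId = as.character(treeId),
      leafType = leafType, pixelScale = pixelScale, flags = flags)
}

#' Create a Sad1Params object
#' @param phi antedependence coefficient.
#' @param nu2 innovation variance (> 0).
#' @return a \linkS4class{Sad1Params}.
#' @export
Sad1Params <- function(phi, nu2) new("Sad1Params", phi = phi, nu2 = nu2)

# shoelace signed area of an open-stored polygon (positive = counterclockwise
# in a y-up frame)
.signedArea <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1)
  sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]) / 2
}
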