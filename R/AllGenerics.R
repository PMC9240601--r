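#' @rdname GenotypeData-class
#' @param object,x a GenotypeData
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))
#' @rdname GenotypeData-class
#' @export
setMethod("genotypeCalls", "GenotypeData", function(x) x@calls)

#' @rdname GenotypeData-class
#' @export
setGeneric("snpMeta", function(x) standardGeneric("snpMeta"))
#' @rdname GenotypeData-class
#' @export
setMethod("snpMeta", "GenotypeData", function(x) x@snpMeta)

#' @rdname GenotypeData-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname GenotypeData-class
#' @export
setMethod("sampleIds", "GenotypeData", function(x) x@sampleIds)

#' @rdname GenotypeData-class
#' @export
setMethod("dim", "GenotypeData", function(x) dim(x@calls))

#' Subset a GenotypeData by individuals (i) and/or SNPs (j)
#' @param i,j,drop,... standard subsetting arguments; drop is ignored.
#' @rdname GenotypeData-class
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@calls))
  if (missing(j)) j <- seq_len(ncol(x@calls))
  new("GenotypeData", calls = x@calls[i, j, drop = FALSE],
      snpMeta = x@snpMeta[j, , drop = FALSE],
      sampleIds = x@sampleIds[i])
})

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object@calls), "individuals x",
      ncol(object@calls), "SNPs\n")
  nm <- sum(is.na(object@calls))
  cat("  chromosomes:", length(unique(object@snpMeta$chrom)),
      " missing calls:", nm,
      sprintf("(%.2f%%)\n", 100 * nm / max(1, length(object@calls))))
})

#' @rdname KinshipMatrix-class
#' @param x a KinshipMatrix
#' @export
setGeneric("kinshipValues", function(x) standardGeneric("kinshipValues"))
#' @rdname KinshipMatrix-class
#' @export
setMethod("kinshipValues", "KinshipMatrix", function(x) x@values)

#' @rdname KinshipMatrix-class
#' @export
setGeneric("kinshipEstimator", function(x) standardGeneric("kinshipEstimator"))
#' @rdname KinshipMatrix-class
#' @export
setMethod("kinshipEstimator", "KinshipMatrix", function(x) x@estimator)

setMethod("show", "KinshipMatrix", function(object) {
  cat("KinshipMatrix (", object@estimator, "): ",
      nrow(object@values), " individuals\n", sep = "")
})

#' @rdname LeafOutline-class
#' @param x a LeafOutline
#' @export
setGeneric("outlinePoints", function(x) standardGeneric("outlinePoints"))
#' @rdname LeafOutline-class
#' @export
setMethod("outlinePoints", "LeafOutline", function(x) x@points)

#' @rdname LeafOutline-class
#' @export
setGeneric("leafType", function(x) standardGeneric("leafType"))
#' @rdname LeafOutline-class
#' @export
setMethod("leafType", "LeafOutline", function(x) x@leafType)

#' @rdname LeafOutline-class
#' @export
setGeneric("treeId", function(x) standardGeneric("treeId"))
#' @rdname LeafOutline-class
#' @export
setMethod("treeId", "LeafOutline", function(x) x@treeId)

setMethod("show", "LeafOutline", function(object) {
  cat("LeafOutline (", object@leafType, "): ", nrow(object@points),
      " vertices", sep = "")
  if (!is.na(object@treeId)) cat(", tree ", object@treeId, sep = "")
  if (length(object@flags)) cat(" [", paste(object@flags, collapse = ","), "]",
                                sep = "")
  cat("\n")
})

#' @rdname EFDescriptor-class
#' @param x an EFDescriptor
#' @export
setGeneric("efHarmonics", function(x) standardGeneric("efHarmonics"))
#' @rdname EFDescriptor-class
#' @export
setMethod("efHarmonics", "EFDescriptor", function(x) x@harmonics)

setMethod("show", "EFDescriptor", function(object) {
  cat("EFDescriptor:", nrow(object@harmonics), "harmonics, centroid (",
      sprintf("%.3g, %.3g", object@dcTerms[1], object@dcTerms[2]), ")\n")
})

setMethod("show", "Sad1Params", function(object) {
  cat(sprintf("SAD(1) parameters: phi = %.4g, nu2 = %.4g\n",
              object@phi, object@nu2))
})

#' @rdname ShapePCA-class
#' @param x a ShapePCA
#' @export
setGeneric("shapeScores", function(x) standardGeneric("shapeScores"))
#' @rdname ShapePCA-class
#' @export
setMethod("shapeScores", "ShapePCA", function(x) x@scores)

#' @rdname ShapePCA-class
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))
#' @rdname ShapePCA-class
#' @export
setMethod("explainedVariance", "ShapePCA", function(x) x@explained)

setMethod("show", "ShapePCA", function(object) {
  cat("ShapePCA:", ncol(object@loadings), "components retained (",
      sprintf("%.1f%%", 100 * sum(object@explained)),
      "of variance, threshold",
      sprintf("%.0f%%", 100 * object@cumThreshold), ")\n")
})
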