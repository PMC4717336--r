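#' @include AllClasses.R
NULL

#' Accessors for barcodeSim S4 objects
#'
#' Small accessor generics so user code never reaches into slots:
#' `distValues()` returns the plain distance matrix, `scaleTag()` its scale
#' ("jc_raw" or "normalized"), `estimatorName()` and `sampleSizes()` describe
#' a schedule or result, `resampleValues()` returns the replicate x size
#' value grid, and `mmConstants()` the fitted Michaelis-Menten constants
#' `c(a, b)`.
#'
#' @param x,fit a barcodeSim object.
#' @return see the individual descriptions above.
#' @name accessors
#' @aliases distValues scaleTag estimatorName sampleSizes resampleValues
#'   mmConstants
NULL

#' @rdname accessors
#' @export
setGeneric("distValues", function(x) standardGeneric("distValues"))

#' @rdname accessors
#' @export
setGeneric("scaleTag", function(x) standardGeneric("scaleTag"))

#' @rdname accessors
#' @export
setGeneric("estimatorName", function(x) standardGeneric("estimatorName"))

#' @rdname accessors
#' @export
setGeneric("sampleSizes", function(x) standardGeneric("sampleSizes"))

#' @rdname accessors
#' @export
setGeneric("resampleValues", function(x) standardGeneric("resampleValues"))

#' @rdname accessors
#' @export
setGeneric("mmConstants", function(fit) standardGeneric("mmConstants"))

#' @rdname accessors
setMethod("distValues", "JCDistanceMatrix", function(x) x@values)

#' @rdname accessors
setMethod("scaleTag", "JCDistanceMatrix", function(x) x@scaleTag)

#' @rdname accessors
setMethod("estimatorName", "SubsampleSchedule", function(x) x@estimator)

#' @rdname accessors
setMethod("estimatorName", "ResampleResult", function(x) x@estimator)

#' @rdname accessors
setMethod("sampleSizes", "SubsampleSchedule", function(x) x@sizes)

#' @rdname accessors
setMethod("sampleSizes", "ResampleResult", function(x) x@sizes)

#' @rdname accessors
setMethod("resampleValues", "ResampleResult", function(x) x@values)

#' @rdname accessors
setMethod("mmConstants", "MMFit", function(fit) c(a = fit@a, b = fit@b))

setMethod("show", "JCDistanceMatrix", function(object) {
  n <- nrow(object@values)
  off <- object@values[upper.tri(object@values)]
  cat(sprintf("JCDistanceMatrix: %d sequences, %d pairwise distances (%s)\n",
              n, length(off), object@scaleTag))
  if (length(off))
    cat(sprintf("  range: [%.6f, %.6f]  mean: %.6f\n",
                min(off), max(off), mean(off)))
  if (object@scaleTag == "normalized")
    cat(sprintf("  normalized from [%.6f, %.6f] to [%.2f, %.2f]\n",
                object@sourceRange[1], object@sourceRange[2],
                object@targetRange[1], object@targetRange[2]))
})

setMethod("show", "SubsampleSchedule", function(object) {
  cat(sprintf("SubsampleSchedule: %s, sizes {%s}, %d replicates, seed %d\n",
              object@estimator, paste(object@sizes, collapse = ","),
              object@replicates, object@seed))
})

setMethod("show", "ResampleResult", function(object) {
  cat(sprintf("ResampleResult: %s on dataset %s\n  %d replicates x sizes {%s}\n",
              object@estimator, object@datasetId, nrow(object@values),
              paste(object@sizes, collapse = ",")))
})

setMethod("show", "MismatchSummary", function(object) {
  cat(sprintf("MismatchSummary: %d distances in %d bins over [%.4g, %.4g]\n",
              object@nValues, length(object@counts),
              min(object@binEdges), max(object@binEdges)))
})

setMethod("show", "MMFit", function(object) {
  cat(sprintf(
    "MMFit: F(x) = a x / (1 + b x), a = %.6g, b = %.6g\n", object@a, object@b))
  cat(sprintf("  asymptote a/b = %.4g, residual variance = %.4g (%d points)\n",
              object@a / object@b, object@residualVariance, object@nPoints))
})

setMethod("show", "StudyConfig", function(object) {
  cat(sprintf("StudyConfig: %d datasets (n = %s)\n",
              nrow(object@datasets),
              paste(object@datasets$n, collapse = ",")))
  cat(sprintf("  theta = %g, L = %d bp, divergence cap = %g, root seed = %d\n",
              object@theta, object@seqLength, object@divergenceCap,
              object@rootSeed))
})
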