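#' @import methods
NULL

#' Pairwise Jukes-Cantor distance matrix
#'
#' Symmetric matrix of pairwise distances among aligned sequences, either
#' raw Jukes-Cantor corrected distances (`scaleTag = "jc_raw"`, units:
#' expected substitutions/site) or min-max normalized distances
#' (`scaleTag = "normalized"`). For normalized matrices the source and
#' target ranges of the linear map are retained so the transformation is
#' auditable.
#'
#' @slot values symmetric numeric matrix, zero diagonal, labelled dimnames.
#' @slot scaleTag `"jc_raw"` or `"normalized"`.
#' @slot sourceRange numeric(2): off-diagonal (min, max) the normalization
#'   mapped from (NA for raw matrices).
#' @slot targetRange numeric(2): (new_min, new_max) mapped to (NA for raw).
#' @exportClass JCDistanceMatrix
setClass("JCDistanceMatrix",
  representation(
    values = "matrix",
    scaleTag = "character",
    sourceRange = "numeric",
    targetRange = "numeric"
  ),
  prototype(
    scaleTag = "jc_raw",
    sourceRange = c(NA_real_, NA_real_),
    targetRange = c(NA_real_, NA_real_)
  )
)

setValidity("JCDistanceMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v) || nrow(v) != ncol(v))
    msg <- c(msg, "'values' must be a square numeric matrix")
  else {
    if (any(is.na(v))) msg <- c(msg, "distances must not be NA")
    else {
      if (max(abs(v - t(v))) > 1e-12) msg <- c(msg, "matrix must be symmetric")
      if (any(diag(v) != 0)) msg <- c(msg, "diagonal must be zero")
      if (min(v) < -1e-12) msg <- c(msg, "distances must be nonnegative")
    }
    if (is.null(rownames(v))) msg <- c(msg, "matrix must carry sequence labels")
  }
  if (!object@scaleTag %in% c("jc_raw", "normalized"))
    msg <- c(msg, "scaleTag must be 'jc_raw' or 'normalized'")
  if (length(msg)) msg else TRUE
})

#' Subsampling schedule
#'
#' Declares which estimator is resampled, at which subsample sizes, how many
#' replicates per size, and the seed of the schedule's RNG substream.
#'
#' @slot estimator one of `"mismatch"`, `"diversity"`, `"haplotypes"`,
#'   `"maxdist"`.
#' @slot sizes strictly increasing integer subsample sizes.
#' @slot replicates replicates per size.
#' @slot seed integer substream seed.
#' @exportClass SubsampleSchedule
setClass("SubsampleSchedule",
  representation(
    estimator = "character",
    sizes = "integer",
    replicates = "integer",
    seed = "integer"
  )
)

setValidity("SubsampleSchedule", function(object) {
  msg <- character()
  if (!object@estimator %in% c("mismatch", "diversity", "haplotypes", "maxdist"))
    msg <- c(msg, "unknown estimator")
  if (length(object@sizes) < 1L || any(object@sizes < 2L) ||
      is.unsorted(object@sizes, strictly = TRUE))
    msg <- c(msg, "sizes must be strictly increasing integers >= 2")
  if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Resampling result grid
#'
#' Estimator values on the complete (replicate x size) grid produced by
#' [runSchedule()]. For the scalar estimators (diversity, haplotypes,
#' maxdist) `values[r, s]` is the estimator of replicate `r` at the s-th
#' subsample size. For the mismatch estimator each replicate keeps its full
#' vector of subsample pairwise distances in `details` and `values` records
#' the replicate's number of interior gaps (empty-bin runs).
#'
#' @slot estimator estimator name.
#' @slot sizes subsample sizes (columns of `values`).
#' @slot values numeric matrix, replicates x sizes.
#' @slot details list (per size) of lists (per replicate) of numeric
#'   vectors; empty except for the mismatch estimator.
#' @slot datasetId character label of the source dataset.
#' @slot seed schedule seed the grid was generated from.
#' @exportClass ResampleResult
setClass("ResampleResult",
  representation(
    estimator = "character",
    sizes = "integer",
    values = "matrix",
    details = "list",
    datasetId = "character",
    seed = "integer"
  ),
  prototype(details = list(), datasetId = NA_character_)
)

setValidity("ResampleResult", function(object) {
  msg <- character()
  if (ncol(object@values) != length(object@sizes))
    msg <- c(msg, "one column of values per subsample size required")
  if (any(is.na(object@values)))
    msg <- c(msg, "the replicate grid must be complete (no NA)")
  if (length(msg)) msg else TRUE
})

#' Mismatch-distribution summary
#'
#' Histogram plus Gaussian kernel density estimate of a set of pairwise
#' distances, the representation behind mismatch-distribution comparisons.
#'
#' @slot binEdges increasing bin edges; bins are half-open `[e, e+w)`, the
#'   last bin closed.
#' @slot counts nonnegative integer counts per bin.
#' @slot kdeGrid evaluation grid of the kernel density estimate.
#' @slot kdeDensity density values on `kdeGrid`.
#' @slot nValues number of distances summarised.
#' @exportClass MismatchSummary
setClass("MismatchSummary",
  representation(
    binEdges = "numeric",
    counts = "integer",
    kdeGrid = "numeric",
    kdeDensity = "numeric",
    nValues = "integer"
  )
)

setValidity("MismatchSummary", function(object) {
  msg <- character()
  if (length(object@binEdges) != length(object@counts) + 1L)
    msg <- c(msg, "need one more edge than bins")
  if (is.unsorted(object@binEdges, strictly = TRUE))
    msg <- c(msg, "bin edges must be strictly increasing")
  if (any(object@counts < 0L)) msg <- c(msg, "counts must be nonnegative")
  if (sum(object@counts) != object@nValues)
    msg <- c(msg, "counts must sum to the number of values")
  if (any(object@kdeDensity < 0)) msg <- c(msg, "kde density must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Michaelis-Menten fit of haplotype accumulation
#'
#' Least-squares fit of the saturation curve F(x) = a x / (1 + b x) to
#' median haplotype counts as a function of subsample size x. The asymptote
#' is a/b and the slope at x is a/(1+bx)^2.
#'
#' @slot a,b fitted constants.
#' @slot residualVariance residual sum of squares / (n_points - 2).
#' @slot nPoints number of (size, median) points fitted.
#' @slot sizes,medians the fitted data, kept for inspection.
#' @exportClass MMFit
setClass("MMFit",
  representation(
    a = "numeric",
    b = "numeric",
    residualVariance = "numeric",
    nPoints = "integer",
    sizes = "numeric",
    medians = "numeric"
  )
)

setValidity("MMFit", function(object) {
  msg <- character()
  if (object@nPoints < 3L) msg <- c(msg, "a fit needs at least 3 points")
  if (object@residualVariance < 0) msg <- c(msg, "residual variance must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Study configuration
#'
#' Everything [runStudy()] needs: dataset identities and sizes, the
#' population-genetic and sequence parameters, the per-estimator subsampling
#' schedules (per dataset), the root seed, and the output directory.
#'
#' @slot datasets data.frame with columns `id`, `n`.
#' @slot theta population mutation parameter (4 N mu) of the simulated
#'   population; enters only the infinite-sites validation overlay.
#' @slot seqLength alignment length in bp.
#' @slot divergenceCap upper bound on realized maximum pairwise JC distance.
#' @slot schedules named list: for each dataset id, a named list of
#'   `SubsampleSchedule` objects.
#' @slot rootSeed study-level seed; all substreams derive from it.
#' @slot outputDir output directory for [runStudy()].
#' @exportClass StudyConfig
setClass("StudyConfig",
  representation(
    datasets = "data.frame",
    theta = "numeric",
    seqLength = "integer",
    divergenceCap = "numeric",
    schedules = "list",
    rootSeed = "integer",
    outputDir = "character"
  )
)

setValidity("StudyConfig", function(object) {
  msg <- character()
  if (anyDuplicated(object@datasets$id)) msg <- c(msg, "dataset ids must be unique")
  if (object@divergenceCap <= 0) msg <- c(msg, "divergenceCap must be > 0")
  for (id in object@datasets$id) {
    n <- object@datasets$n[object@datasets$id == id]
    for (sch in object@schedules[[id]])
      if (any(sch@sizes > n))
        msg <- c(msg, sprintf("schedule sizes exceed n for dataset %s", id))
  }
  if (length(msg)) msg else TRUE
})

setMethod("$", "StudyConfig", function(x, name) slot(x, name))
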