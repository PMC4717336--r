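#' Proportion of differing sites between two aligned sequences
#'
#' @param a,b character strings or `DNAString`s of equal length.
#' @return the p-distance (proportion of mismatching sites).
#' @export
pDistance <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  mean(av != bv)
}

#' Jukes-Cantor distance correction
#'
#' Converts a proportion of observed differences p into the expected number
#' of substitutions per site under the JC model,
#' d = -(3/4) log(1 - 4p/3). Monotone increasing and >= p on its domain;
#' saturates (diverges) as p approaches 3/4.
#'
#' @param p numeric vector of p-distances in `[0, 0.75)`.
#' @return JC-corrected distances.
#' @examples
#' jcCorrect(0.01)
#' @export
jcCorrect <- function(p) {
  if (any(p < 0)) stop("'p' must be nonnegative")
  if (any(p >= 0.75))
    stop("p-distance at or beyond the JC saturation point 3/4")
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise Jukes-Cantor distance matrix of an alignment
#'
#' Computes all n(n-1)/2 pairwise JC distances of an alignment. Mismatch
#' counts are obtained by indicator cross-products over the four bases
#' (exact, no heuristics), then corrected with [jcCorrect()].
#'
#' @param aln a named `DNAStringSet` (or character vector) of equal-length
#'   ungapped sequences, n >= 2.
#' @return a [JCDistanceMatrix] with `scaleTag = "jc_raw"`.
#' @examples
#' aln <- Biostrings::DNAStringSet(c(s1 = "AAAA", s2 = "AAAT", s3 = "AATT"))
#' distValues(pairwiseMatrix(aln))
#' @export
pairwiseMatrix <- function(aln) {
  chars <- alignmentMatrix(aln)
  n <- nrow(chars)
  if (n < 2L) stop("an alignment of at least 2 sequences is required")
  L <- ncol(chars)
  matches <- matrix(0, n, n)
  for (b in BASES) {
    ind <- chars == b
    storage.mode(ind) <- "double"
    matches <- matches + tcrossprod(ind)
  }
  p <- 1 - matches / L
  diag(p) <- 0
  if (any(p[upper.tri(p)] >= 0.75)) {
    bad <- which(p >= 0.75 & upper.tri(p), arr.ind = TRUE)[1L, ]
    stop(sprintf("pair (%s, %s) is JC-saturated (p = %.3f)",
                 rownames(chars)[bad[1]], rownames(chars)[bad[2]],
                 p[bad[1], bad[2]]))
  }
  d <- -0.75 * log(1 - 4 * p / 3)
  diag(d) <- 0
  d <- (d + t(d)) / 2  # enforce exact symmetry against float noise
  dimnames(d) <- list(rownames(chars), rownames(chars))
  new("JCDistanceMatrix", values = d, scaleTag = "jc_raw")
}

#' Min-max normalization of a distance matrix
#'
#' Linearly maps the off-diagonal distances of a dataset onto a common
#' target interval: d' = (d - min)/(max - min) * (newMax - newMin) + newMin,
#' with min and max taken over the off-diagonal (pairwise) entries only.
#' The default target \[0, 0.03\] puts every dataset on the same 0-3%
#' divergence scale so mismatch distributions are directly comparable. The
#' map is strictly monotone, so the ordering (and ties) of distances is
#' preserved. Subsamples of a normalized matrix are taken as-is, without
#' renormalization.
#'
#' @param m a [JCDistanceMatrix].
#' @param newMin,newMax target range (defaults 0 and 0.03).
#' @return a [JCDistanceMatrix] with `scaleTag = "normalized"`.
#' @export
minmaxNormalize <- function(m, newMin = 0, newMax = 0.03) {
  stopifnot(is(m, "JCDistanceMatrix"))
  if (newMax <= newMin) stop("'newMax' must exceed 'newMin'")
  v <- m@values
  off <- v[upper.tri(v)]
  lo <- min(off)
  hi <- max(off)
  if (hi == lo)
    stop("all pairwise distances are equal; min-max normalization is degenerate")
  w <- (v - lo) / (hi - lo) * (newMax - newMin) + newMin
  diag(w) <- 0
  new("JCDistanceMatrix", values = w, scaleTag = "normalized",
      sourceRange = c(lo, hi), targetRange = c(newMin, newMax))
}

# alignment (DNAStringSet or character) -> labelled character matrix
alignmentMatrix <- function(aln) {
  if (is(aln, "DNAStringSet")) {
    chars <- as.matrix(aln)
  } else if (is.character(aln)) {
    if (length(unique(nchar(aln))) != 1L)
      stop("sequences must have equal length")
    chars <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
    rownames(chars) <- names(aln)
  } else stop("'aln' must be a DNAStringSet or character vector")
  if (is.null(rownames(chars)))
    rownames(chars) <- paste0("s", seq_len(nrow(chars)))
  chars
}
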