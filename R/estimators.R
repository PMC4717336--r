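#' Nucleotide diversity (mean pairwise distance)
#'
#' The average of all k = s(s-1)/2 pairwise distances among the members of
#' `subset` (default: all sequences). On JC or normalized distances this is
#' the within-population nucleotide diversity pi; over the full dataset it
#' is the reference value beta that subsample estimates are compared to.
#'
#' @param m a [JCDistanceMatrix].
#' @param subset integer indices of the sequences to include (>= 2 of them);
#'   defaults to all.
#' @return mean pairwise distance among the subset.
#' @export
nucleotideDiversity <- function(m, subset = NULL) {
  stopifnot(is(m, "JCDistanceMatrix"))
  v <- m@values
  if (is.null(subset)) subset <- seq_len(nrow(v))
  s <- length(subset)
  if (s < 2L) stop("nucleotide diversity needs at least 2 sequences")
  sub <- v[subset, subset]
  sum(sub) / (s * (s - 1))
}

#' Maximum pairwise distance within a subset
#'
#' @param m a [JCDistanceMatrix].
#' @param subset integer indices (>= 2); defaults to all sequences.
#' @return the largest pairwise distance among the subset; never exceeds the
#'   full-matrix maximum.
#' @export
maxPairwise <- function(m, subset = NULL) {
  stopifnot(is(m, "JCDistanceMatrix"))
  v <- m@values
  if (is.null(subset)) subset <- seq_len(nrow(v))
  if (length(subset) < 2L) stop("at least 2 sequences are required")
  max(v[subset, subset])
}

#' Number of distinct haplotypes in a subset
#'
#' Counts distinct sequence strings by exact identity (the simulated data
#' contain no gaps or ambiguity codes, so exact matching is the appropriate
#' haplotype definition).
#'
#' @param aln a `DNAStringSet` or character vector of aligned sequences.
#' @param subset integer indices (>= 1); defaults to all sequences.
#' @return integer haplotype count, between 1 and `length(subset)`.
#' @export
countHaplotypes <- function(aln, subset = NULL) {
  sq <- as.character(aln)
  if (is.null(subset)) subset <- seq_along(sq)
  if (length(subset) < 1L) stop("'subset' must be nonempty")
  length(unique(sq[subset]))
}

#' Mismatch distribution: histogram and kernel density estimate
#'
#' Bins a set of pairwise distances into half-open bins `[e, e+w)` (last bin
#' closed) spanning at least \[0, 0.03\] — the normalized divergence scale —
#' and overlays a Gaussian kernel density estimate with Silverman's
#' rule-of-thumb bandwidth on a 512-point grid.
#'
#' @param values nonempty numeric vector of pairwise distances.
#' @param binWidth histogram bin width (default 0.001, i.e. 30 bins across
#'   the normalized 0-3% range).
#' @param range lower/upper bounds of the binned interval; extended upward
#'   automatically if values exceed it.
#' @return a [MismatchSummary].
#' @export
mismatchHistogram <- function(values, binWidth = 0.001, range = c(0, 0.03)) {
  if (length(values) == 0L) stop("'values' must be nonempty")
  if (binWidth <= 0) stop("'binWidth' must be > 0")
  if (any(values < range[1]))
    stop("values below the lower bin edge")
  hi <- max(range[2], max(values))
  nBin <- ceiling((hi - range[1]) / binWidth - 1e-9)
  edges <- range[1] + binWidth * (0:nBin)
  idx <- pmin(floor((values - range[1]) / binWidth) + 1L, nBin)  # last bin closed
  counts <- tabulate(idx, nbins = nBin)
  spread <- if (length(values) > 1L) stats::sd(values) else 0
  bw <- if (spread > 0) stats::bw.nrd0(values) else binWidth / 4
  kde <- stats::density(values, bw = bw, n = 512L)
  new("MismatchSummary", binEdges = edges, counts = as.integer(counts),
      kdeGrid = kde$x, kdeDensity = kde$y, nValues = length(values))
}

#' Count modes of a mismatch distribution
#'
#' Local maxima of the kernel density curve, with a guard against counting
#' numerical ripples as modes. By default a maximum counts if its height
#' reaches `minFrac` of the global peak. With `prominence = TRUE` the guard
#' is applied to the peak's topographic prominence instead (its height above
#' the higher of the valleys separating it from taller peaks) — the
#' appropriate notion when asking whether a distribution is genuinely
#' multimodal rather than bell-shaped with shoulder bumps. Under a
#' constant-size coalescent, full-dataset mismatch distributions are
#' typically bimodal or multimodal.
#'
#' @param ms a [MismatchSummary].
#' @param minFrac minimum peak height (or prominence) as a fraction of the
#'   maximum density (default 0.01).
#' @param prominence apply the guard to peak prominence instead of height.
#' @return integer number of modes.
#' @export
modeCount <- function(ms, minFrac = 0.01, prominence = FALSE) {
  stopifnot(is(ms, "MismatchSummary"))
  y <- ms@kdeDensity
  n <- length(y)
  peak <- max(y)
  isMax <- c(y[1] > y[2],
             y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
             y[n] > y[n - 1])
  locs <- which(isMax)
  if (!prominence) return(sum(y[locs] >= minFrac * peak))
  prom <- vapply(locs, function(p) {
    base <- function(step) {
      i <- p
      mn <- y[p]
      repeat {
        i <- i + step
        if (i < 1L || i > n) break
        mn <- min(mn, y[i])
        if (y[i] > y[p]) break
      }
      mn
    }
    y[p] - max(base(-1L), base(1L))
  }, numeric(1))
  sum(prom >= minFrac * peak)
}

#' Gaps in a mismatch distribution
#'
#' Maximal runs of consecutive empty bins inside the binned range, reported
#' as (start edge, end edge) intervals. Gaps between intra-group distance
#' clusters are a direct consequence of long basal coalescent branches, and
#' subsamples typically show additional gaps relative to the full dataset.
#'
#' @inheritParams mismatchHistogram
#' @return data.frame with columns `start`, `end`; zero rows when every bin
#'   is occupied.
#' @export
gapReport <- function(values, binWidth = 0.001, range = c(0, 0.03)) {
  ms <- mismatchHistogram(values, binWidth = binWidth, range = range)
  gapRuns(ms)
}

# maximal zero-count runs of an existing histogram
gapRuns <- function(ms) {
  counts <- ms@counts
  edges <- ms@binEdges
  out <- data.frame(start = numeric(0), end = numeric(0))
  zero <- which(counts == 0L)
  if (!length(zero)) return(out)
  breaks <- c(0L, which(diff(zero) > 1L), length(zero))
  for (i in seq_len(length(breaks) - 1L)) {
    run <- zero[(breaks[i] + 1L):breaks[i + 1L]]
    out <- rbind(out, data.frame(start = edges[run[1L]],
                                 end = edges[run[length(run)] + 1L]))
  }
  out
}
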