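#' Construct a subsampling schedule
#'
#' @param estimator one of `"mismatch"`, `"diversity"`, `"haplotypes"`,
#'   `"maxdist"`.
#' @param sizes strictly increasing subsample sizes (>= 2).
#' @param replicates replicates per size.
#' @param seed integer seed of the schedule's RNG substream.
#' @return a [SubsampleSchedule].
#' @export
subsampleSchedule <- function(estimator, sizes, replicates, seed = 1L) {
  new("SubsampleSchedule", estimator = estimator,
      sizes = as.integer(sizes), replicates = as.integer(replicates),
      seed = as.integer(seed))
}

#' Draw a uniform random subsample of indices
#'
#' Sampling is without replacement — a subsample represents distinct
#' individuals — and uniform over all size-`size` subsets. Distinct
#' replicates may still repeat the same subset by chance.
#'
#' @param nTotal number of sequences in the dataset.
#' @param size subsample size, `2 <= size <= nTotal`.
#' @return integer vector of `size` distinct indices in `1:nTotal`.
#' @export
drawSubsample <- function(nTotal, size) {
  if (size < 2 || size > nTotal)
    stop("'size' must satisfy 2 <= size <= nTotal")
  sample.int(nTotal, size)
}

#' Run a subsampling schedule over a dataset
#'
#' For every (size, replicate) cell an independent subsample is drawn and
#' the scheduled estimator evaluated on it, producing a complete
#' replicates-by-sizes grid. Each subsample size runs in its own derived RNG
#' substream, so the grid is reproducible from the schedule seed and any
#' single size can be re-run independently.
#'
#' For the `mismatch` estimator each replicate's subsample pairwise
#' distances are retained in the result's `details`; the value grid then
#' holds the replicate's interior-gap count (see [gapReport()]).
#'
#' @param aln alignment (`DNAStringSet`), required for the haplotypes
#'   estimator.
#' @param m [JCDistanceMatrix], required for the distance-based estimators.
#' @param sched a [SubsampleSchedule].
#' @param datasetId optional label stored in the result.
#' @return a [ResampleResult].
#' @export
runSchedule <- function(aln = NULL, m = NULL, sched, datasetId = NA_character_) {
  stopifnot(is(sched, "SubsampleSchedule"))
  est <- sched@estimator
  if (est == "haplotypes") {
    if (is.null(aln)) stop("the haplotypes estimator requires an alignment")
    nTotal <- length(as.character(aln))
  } else {
    if (is.null(m)) stop(sprintf("the %s estimator requires a distance matrix", est))
    nTotal <- nrow(m@values)
  }
  if (any(sched@sizes > nTotal))
    stop("schedule sizes exceed the dataset size")
  nRep <- sched@replicates
  vals <- matrix(NA_real_, nRep, length(sched@sizes))
  colnames(vals) <- sched@sizes
  details <- list()
  for (si in seq_along(sched@sizes)) {
    size <- sched@sizes[si]
    sizeSeed <- deriveSeed(sched@seed, si)
    col <- withSeed(sizeSeed, {
      if (est == "mismatch") detailCol <- vector("list", nRep)
      out <- numeric(nRep)
      for (r in seq_len(nRep)) {
        idx <- drawSubsample(nTotal, size)
        out[r] <- switch(est,
          diversity = nucleotideDiversity(m, idx),
          maxdist = maxPairwise(m, idx),
          haplotypes = countHaplotypes(aln, idx),
          mismatch = {
            sub <- m@values[idx, idx]
            dd <- sub[upper.tri(sub)]
            detailCol[[r]] <- dd
            nrow(gapReport(dd))
          })
      }
      if (est == "mismatch") list(out = out, det = detailCol)
      else list(out = out, det = NULL)
    })
    vals[, si] <- col$out
    if (!is.null(col$det)) details[[as.character(size)]] <- col$det
  }
  new("ResampleResult", estimator = est, sizes = sched@sizes, values = vals,
      details = details, datasetId = datasetId, seed = sched@seed)
}

#' Per-size band summary of diversity estimates
#'
#' For each subsample size, the mean of the replicate estimates and the
#' percentage falling in the closed band `beta +/- halfWidth`, where beta is
#' the full-dataset nucleotide diversity. The band percentage is the
#' headline statistic for how reliably a given sample size recovers the
#' population diversity.
#'
#' @param r a diversity-type [ResampleResult].
#' @param beta full-dataset nucleotide diversity.
#' @param halfWidth half-width of the band (default 0.001); the comparison
#'   uses unrounded values.
#' @return data.frame with columns `size`, `mean`, `pctInBand`,
#'   `bandHalfWidth`.
#' @export
bandSummary <- function(r, beta, halfWidth = 0.001) {
  stopifnot(is(r, "ResampleResult"))
  pct <- vapply(seq_along(r@sizes), function(si) {
    100 * mean(abs(r@values[, si] - beta) <= halfWidth)
  }, numeric(1))
  data.frame(size = r@sizes, mean = colMeans(r@values), pctInBand = pct,
             bandHalfWidth = halfWidth, row.names = NULL)
}

#' Central-limit diagnostics of diversity estimates
#'
#' Per-size mean, variance and skewness of the replicate estimates. As k =
#' s(s-1)/2 pairwise comparisons grow, the estimates are expected to
#' concentrate around beta with shrinking variance and skewness
#' (bell-shaped for sizes >= 20). Degenerate (constant) cells report zero
#' skewness with `degenerate = TRUE`.
#'
#' @param r a diversity-type [ResampleResult].
#' @param beta full-dataset diversity, carried through in the output.
#' @return data.frame with columns `size`, `mean`, `variance`, `skewness`,
#'   `degenerate`, `beta`.
#' @export
cltDiagnostics <- function(r, beta = NA_real_) {
  stopifnot(is(r, "ResampleResult"))
  rows <- lapply(seq_along(r@sizes), function(si) {
    x <- r@values[, si]
    v <- stats::var(x)
    sk <- sampleSkewness(x)
    data.frame(size = r@sizes[si], mean = mean(x), variance = v,
               skewness = if (is.na(sk)) 0 else sk,
               degenerate = is.na(sk), beta = beta)
  })
  do.call(rbind, rows)
}

#' Five-number summary per subsample size
#'
#' Minimum, first quartile, median, third quartile and maximum of the
#' replicate values at each size (the boxplot statistics of haplotype
#' accumulation). The median uses the midpoint convention for even counts;
#' quartiles use linear interpolation.
#'
#' @param r a [ResampleResult].
#' @return data.frame with columns `size`, `min`, `q1`, `median`, `q3`,
#'   `max`.
#' @export
quartileSummary <- function(r) {
  stopifnot(is(r, "ResampleResult"))
  rows <- lapply(seq_along(r@sizes), function(si) {
    x <- r@values[, si]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(size = r@sizes[si], min = min(x), q1 = q[1], median = q[2],
               q3 = q[3], max = max(x))
  })
  do.call(rbind, rows)
}

#' Fit a Michaelis-Menten curve to median haplotype counts
#'
#' Least-squares fit of F(x) = a x / (1 + b x) to the median number of
#' haplotypes as a function of subsample size x. Starting values come from
#' ordinary least squares on the linearization 1/F = (1/a)(1/x) + b/a; the
#' nonlinear refinement uses Levenberg-Marquardt. The residual variance is
#' RSS / (nPoints - 2), two constants having been fitted.
#'
#' @param sizes positive subsample sizes (>= 3 of them).
#' @param medians median haplotype counts at those sizes.
#' @return an [MMFit].
#' @examples
#' x <- c(2, seq(10, 150, 10))
#' fitMichaelisMenten(x, 2 * x / (1 + 0.05 * x))
#' @export
fitMichaelisMenten <- function(sizes, medians) {
  if (length(sizes) != length(medians)) stop("lengths differ")
  if (length(sizes) < 3L) stop("at least 3 points are required")
  if (any(sizes <= 0)) stop("sizes must be positive")
  pos <- medians > 0
  a0 <- b0 <- NA_real_
  if (sum(pos) >= 2L) {
    lin <- stats::lm(I(1 / medians[pos]) ~ I(1 / sizes[pos]))
    slope <- unname(stats::coef(lin)[2])
    inter <- unname(stats::coef(lin)[1])
    if (is.finite(slope) && slope > 0) {
      a0 <- 1 / slope
      b0 <- inter * a0
    }
  }
  if (!is.finite(a0) || !is.finite(b0) || a0 <= 0) {
    # fallback: initial slope and asymptote read off the data
    a0 <- medians[1] / sizes[1]
    b0 <- max(a0 / max(medians), 1e-6)
  }
  df <- data.frame(x = sizes, y = medians)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * x / (1 + b * x), data = df,
                      start = list(a = a0, b = b0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    co <- stats::coef(fit)
    rss <- sum(stats::residuals(fit)^2)
  } else {
    # Levenberg-Marquardt can fail on degenerate data (e.g. a flat median
    # profile drives a and b jointly to infinity at fixed asymptote a/b);
    # fall back to direct RSS minimization on the log scale, which keeps
    # the constants positive and the asymptote identified
    rssFun <- function(par) {
      sum((medians - exp(par[1]) * sizes / (1 + exp(par[2]) * sizes))^2)
    }
    opt <- stats::optim(c(log(a0), log(max(b0, 1e-8))), rssFun,
                        control = list(maxit = 5000, reltol = 1e-14))
    if (!is.finite(opt$value))
      stop(sprintf(
        "Michaelis-Menten fit failed to converge (start a = %.4g, b = %.4g)",
        a0, b0))
    co <- c(a = exp(opt$par[1]), b = exp(opt$par[2]))
    rss <- opt$value
  }
  new("MMFit", a = unname(co["a"]), b = unname(co["b"]),
      residualVariance = rss / (length(sizes) - 2L),
      nPoints = length(sizes), sizes = as.numeric(sizes),
      medians = as.numeric(medians))
}

#' Slope of a fitted Michaelis-Menten curve
#'
#' Analytic derivative a / (1 + b x)^2 of F(x) = a x / (1 + b x): the rate
#' at which new haplotypes accumulate per added individual at sample size x.
#' Positive and decreasing in x for a, b > 0, with F'(0) = a.
#'
#' @param fit an [MMFit].
#' @param x sample size(s) at which to evaluate the slope.
#' @return numeric slope values.
#' @export
mmSlope <- function(fit, x) {
  stopifnot(is(fit, "MMFit"))
  fit@a / (1 + fit@b * x)^2
}
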