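#' Write / read a distance matrix as labelled CSV
#'
#' Square-matrix CSV with sequence labels in the first row and column.
#' Distances are written at full double precision (any rounding is a
#' formatting decision left to reporting code); the scale tag and, for
#' normalized matrices, the source/target ranges travel in a comment-free
#' side-car convention: a `#scale` header line.
#'
#' @param m a [JCDistanceMatrix].
#' @param path output file.
#' @return `writeDistanceMatrix()` returns `path` invisibly;
#'   `readDistanceMatrix()` returns a [JCDistanceMatrix].
#' @export
writeDistanceMatrix <- function(m, path) {
  stopifnot(is(m, "JCDistanceMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(m@scaleTag, m@sourceRange, m@targetRange)
  writeLines(paste0("#scale,", paste(meta, collapse = ",")), con)
  utils::write.csv(as.data.frame(m@values), con, row.names = TRUE)
  invisible(path)
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- strsplit(sub("^#scale,", "", header), ",")[[1]]
  df <- utils::read.csv(path, skip = 1L, row.names = 1L, check.names = FALSE)
  v <- as.matrix(df)
  colnames(v) <- rownames(v)
  v <- (v + t(v)) / 2
  new("JCDistanceMatrix", values = v, scaleTag = meta[1],
      sourceRange = as.numeric(meta[2:3]), targetRange = as.numeric(meta[4:5]))
}

#' Export a distance matrix in square PHYLIP format
#'
#' @param m a [JCDistanceMatrix].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePhylipDist <- function(m, path) {
  stopifnot(is(m, "JCDistanceMatrix"))
  v <- m@values
  lab <- sprintf("%-10s", substr(rownames(v), 1L, 10L))
  rows <- vapply(seq_len(nrow(v)), function(i) {
    paste0(lab[i], paste(sprintf("%.8f", v[i, ]), collapse = "  "))
  }, character(1))
  writeLines(c(sprintf("%5d", nrow(v)), rows), path)
  invisible(path)
}

#' Write / read a resampling grid as tidy CSV
#'
#' Long format with one row per (size, replicate):
#' `datasetId, estimator, size, replicate, value`. Mismatch details (the
#' per-replicate distance vectors) are not serialized; the scalar grid is.
#'
#' @param r a [ResampleResult].
#' @param path file path.
#' @return `writeResampleResult()` returns `path` invisibly;
#'   `readResampleResult()` returns a [ResampleResult] (without details).
#' @export
writeResampleResult <- function(r, path) {
  stopifnot(is(r, "ResampleResult"))
  nRep <- nrow(r@values)
  df <- data.frame(
    datasetId = r@datasetId,
    estimator = r@estimator,
    size = rep(r@sizes, each = nRep),
    replicate = rep(seq_len(nRep), times = length(r@sizes)),
    value = as.vector(r@values)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeResampleResult
#' @export
readResampleResult <- function(path) {
  df <- utils::read.csv(path)
  sizes <- sort(unique(df$size))
  nRep <- max(df$replicate)
  vals <- matrix(NA_real_, nRep, length(sizes))
  colnames(vals) <- sizes
  for (si in seq_along(sizes)) {
    sub <- df[df$size == sizes[si], ]
    vals[sub$replicate, si] <- sub$value
  }
  new("ResampleResult", estimator = df$estimator[1],
      sizes = as.integer(sizes), values = vals,
      datasetId = as.character(df$datasetId[1]), seed = NA_integer_)
}

#' Export a mismatch summary as tidy CSV
#'
#' Two stacked tables in one file: histogram rows
#' (`part = "hist"`, `binLeft`, `binRight`, `count`) and kernel-density rows
#' (`part = "kde"`, `grid`, `density`).
#'
#' @param ms a [MismatchSummary].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeMismatchSummary <- function(ms, path) {
  stopifnot(is(ms, "MismatchSummary"))
  nb <- length(ms@counts)
  hist <- data.frame(part = "hist",
                     binLeft = ms@binEdges[seq_len(nb)],
                     binRight = ms@binEdges[-1L],
                     count = ms@counts,
                     grid = NA_real_, density = NA_real_)
  kde <- data.frame(part = "kde", binLeft = NA_real_, binRight = NA_real_,
                    count = NA_integer_, grid = ms@kdeGrid,
                    density = ms@kdeDensity)
  utils::write.csv(rbind(hist, kde), path, row.names = FALSE)
  invisible(path)
}
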