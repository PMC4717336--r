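#' Default study configuration
#'
#' Encodes the full study protocol: ten datasets of 500 sequences (seq_A to
#' seq_J) plus seq_K (300) and seq_L (1000); theta = 3 per locus; 1,500-bp
#' JC sequences with a 3% realized-divergence cap; and the per-estimator
#' subsampling schedules — mismatch sizes \{5,10,20,30,50,100\} x 10
#' replicates; diversity and maximum-distance sizes
#' \{2,5,10,20,...,100\} x 10,000 (truncated at 60 for the two additional
#' datasets); haplotype sizes \{2,10,20,...,150\} x 100 (16 sizes;
#' \{2,20,40,...,140\} for the additional datasets). Schedule seeds are all
#' derived from `rootSeed` so datasets are independent replicates yet the
#' whole study reruns identically.
#'
#' @param rootSeed study-level integer seed.
#' @param outputDir where [runStudy()] writes its outputs.
#' @return a [StudyConfig].
#' @export
defaultConfig <- function(rootSeed = 1L, outputDir = "study_out") {
  ids <- c(paste0("seq_", LETTERS[1:10]), "seq_K", "seq_L")
  ns <- c(rep(500L, 10), 300L, 1000L)
  datasets <- data.frame(id = ids, n = ns, stringsAsFactors = FALSE)
  mainDiv <- c(2L, 5L, 10L, seq(20L, 100L, 10L))
  addDiv <- c(2L, 5L, 10L, 20L, 30L, 40L, 50L, 60L)
  mainHap <- c(2L, seq(10L, 150L, 10L))
  addHap <- c(2L, seq(20L, 140L, 20L))
  schedules <- list()
  for (i in seq_along(ids)) {
    additional <- ns[i] != 500L
    div <- if (additional) addDiv else mainDiv
    hap <- if (additional) addHap else mainHap
    schedules[[ids[i]]] <- list(
      mismatch = subsampleSchedule("mismatch", c(5L, 10L, 20L, 30L, 50L, 100L),
                                   10L, deriveSeed(rootSeed, i, 10L)),
      diversity = subsampleSchedule("diversity", div, 10000L,
                                    deriveSeed(rootSeed, i, 20L)),
      haplotypes = subsampleSchedule("haplotypes", hap, 100L,
                                     deriveSeed(rootSeed, i, 30L)),
      maxdist = subsampleSchedule("maxdist", div, 10000L,
                                  deriveSeed(rootSeed, i, 40L))
    )
  }
  new("StudyConfig", datasets = datasets, theta = 3.0, seqLength = 1500L,
      divergenceCap = 0.03, schedules = schedules,
      rootSeed = as.integer(rootSeed), outputDir = outputDir)
}

#' Build a smaller configuration for quick runs
#'
#' Same pipeline and output contract as [defaultConfig()] but with
#' user-chosen dataset sizes and replicate counts, for smoke tests and
#' desk-scale reruns.
#'
#' @param datasets data.frame with columns `id`, `n`.
#' @param replicates named list overriding replicate counts, e.g.
#'   `list(diversity = 1000)`.
#' @param sizes named list overriding size vectors per estimator.
#' @inheritParams defaultConfig
#' @return a [StudyConfig].
#' @export
smokeConfig <- function(datasets = data.frame(id = c("toy_A", "toy_B"),
                                              n = c(30L, 30L)),
                        replicates = list(mismatch = 5L, diversity = 200L,
                                          haplotypes = 50L, maxdist = 200L),
                        sizes = list(mismatch = c(5L, 10L),
                                     diversity = c(2L, 5L, 10L, 20L),
                                     haplotypes = c(2L, 5L, 10L, 20L),
                                     maxdist = c(2L, 5L, 10L, 20L)),
                        rootSeed = 1L, outputDir = "study_out") {
  schedules <- list()
  for (i in seq_len(nrow(datasets))) {
    id <- datasets$id[i]
    schedules[[id]] <- list(
      mismatch = subsampleSchedule("mismatch", sizes$mismatch,
                                   replicates$mismatch, deriveSeed(rootSeed, i, 10L)),
      diversity = subsampleSchedule("diversity", sizes$diversity,
                                    replicates$diversity, deriveSeed(rootSeed, i, 20L)),
      haplotypes = subsampleSchedule("haplotypes", sizes$haplotypes,
                                     replicates$haplotypes, deriveSeed(rootSeed, i, 30L)),
      maxdist = subsampleSchedule("maxdist", sizes$maxdist,
                                  replicates$maxdist, deriveSeed(rootSeed, i, 40L))
    )
  }
  new("StudyConfig", datasets = datasets, theta = 3.0, seqLength = 1500L,
      divergenceCap = 0.03, schedules = schedules,
      rootSeed = as.integer(rootSeed), outputDir = outputDir)
}

#' Generate one dataset of the study
#'
#' Runs the synthetic-data stages for a single dataset: coalescent
#' genealogy, divergence-capped rescaling and JC sequence evolution, raw and
#' normalized distance matrices, and tree-shape diagnostics.
#'
#' @param n number of sequences.
#' @param cfg a [StudyConfig] supplying theta, sequence length and cap.
#' @param genSeed,seqSeed seeds of the genealogy and sequence substreams.
#' @return list with `tree` (coalescent units), `scaledTree`, `alignment`,
#'   `raw` and `normalized` [JCDistanceMatrix] objects, `beta`
#'   (full-dataset diversity on the normalized scale), `colless`
#'   (normalized), and `splitProfile`.
#' @export
simulateDataset <- function(n, cfg, genSeed, seqSeed) {
  g <- simulateGenealogy(n, seed = genSeed)
  capres <- enforceDivergenceCap(g, L = cfg@seqLength, cap = cfg@divergenceCap,
                                 seed = seqSeed)
  normalized <- minmaxNormalize(capres$matrix, 0, cfg@divergenceCap)
  list(
    tree = g,
    scaledTree = capres$tree,
    alignment = capres$alignment,
    raw = capres$matrix,
    normalized = normalized,
    beta = nucleotideDiversity(normalized),
    colless = if (n >= 3) collessIndex(g, normalized = TRUE) else NA_real_,
    splitProfile = aldousSplitProfile(g, k = min(7L, n - 1L))
  )
}

#' Run the full simulation study
#'
#' Executes the complete protocol described by a [StudyConfig]: for every
#' dataset it simulates the genealogy and alignment, writes Newick/FASTA and
#' distance CSVs, runs all four subsampling schedules, and writes the
#' summary tables (band summary and CLT diagnostics for diversity, quartile
#' table plus Michaelis-Menten fit for haplotypes, quartile and
#' full-max-recovery table for maximum distance, histogram/KDE/gap tables
#' for the mismatch distribution) together with a JSON run manifest holding
#' every derived seed. A failing dataset is logged and skipped; the returned
#' object records the failures.
#'
#' @param cfg a [StudyConfig].
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list with `outputDir`, per-dataset summaries
#'   (`beta`, `colless`, `maxDistance`, `mmFit`), and `failures` (character
#'   vector of failed dataset ids).
#' @export
runStudy <- function(cfg, quiet = FALSE) {
  stopifnot(is(cfg, "StudyConfig"))
  dir.create(cfg@outputDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(rootSeed = cfg@rootSeed, theta = cfg@theta,
                   seqLength = cfg@seqLength, divergenceCap = cfg@divergenceCap,
                   datasets = list())
  results <- list()
  failures <- character(0)
  say <- function(...) if (!quiet) message(sprintf(...))
  for (i in seq_len(nrow(cfg@datasets))) {
    id <- cfg@datasets$id[i]
    n <- cfg@datasets$n[i]
    genSeed <- deriveSeed(cfg@rootSeed, i, 1L)
    seqSeed <- deriveSeed(cfg@rootSeed, i, 2L)
    t0 <- proc.time()[3]
    res <- tryCatch({
      dsDir <- file.path(cfg@outputDir, id)
      dir.create(dsDir, showWarnings = FALSE)
      say("[%s] simulating n = %d", id, n)
      ds <- simulateDataset(n, cfg, genSeed, seqSeed)
      ape::write.tree(ds$scaledTree, file.path(dsDir, "genealogy.nwk"))
      Biostrings::writeXStringSet(ds$alignment,
                                  file.path(dsDir, "alignment.fasta"),
                                  width = 80L)
      writeDistanceMatrix(ds$raw, file.path(dsDir, "distances_raw.csv"))
      writeDistanceMatrix(ds$normalized,
                          file.path(dsDir, "distances_normalized.csv"))
      utils::write.csv(
        data.frame(stat = c("colless_raw", "colless_normalized", "beta",
                            "max_distance"),
                   value = c(if (n >= 3) collessIndex(ds$tree) else NA,
                             ds$colless, ds$beta, maxPairwise(ds$normalized))),
        file.path(dsDir, "treeshape.csv"), row.names = FALSE)
      utils::write.csv(ds$splitProfile,
                       file.path(dsDir, "split_profile.csv"), row.names = FALSE)
      summary <- list(beta = ds$beta, colless = ds$colless,
                      maxDistance = maxPairwise(ds$normalized), mmFit = NULL)
      for (sch in cfg@schedules[[id]]) {
        say("[%s] resampling: %s", id, sch@estimator)
        r <- runSchedule(aln = ds$alignment, m = ds$normalized,
                         sched = sch, datasetId = id)
        writeResampleResult(r, file.path(dsDir, paste0(
          "resample_", sch@estimator, ".csv")))
        if (sch@estimator == "diversity") {
          utils::write.csv(bandSummary(r, ds$beta),
                           file.path(dsDir, "band_summary.csv"),
                           row.names = FALSE)
          utils::write.csv(cltDiagnostics(r, ds$beta),
                           file.path(dsDir, "clt_diagnostics.csv"),
                           row.names = FALSE)
        } else if (sch@estimator == "haplotypes") {
          qs <- quartileSummary(r)
          utils::write.csv(qs, file.path(dsDir, "haplotype_quartiles.csv"),
                           row.names = FALSE)
          fit <- fitMichaelisMenten(qs$size, qs$median)
          summary$mmFit <- fit
          utils::write.csv(
            data.frame(a = fit@a, b = fit@b, asymptote = fit@a / fit@b,
                       residualVariance = fit@residualVariance,
                       nPoints = fit@nPoints),
            file.path(dsDir, "mm_fit.csv"), row.names = FALSE)
        } else if (sch@estimator == "maxdist") {
          qs <- quartileSummary(r)
          full <- maxPairwise(ds$normalized)
          qs$pctAtFullMax <- vapply(seq_along(r@sizes), function(si) {
            100 * mean(r@values[, si] >= full - 1e-12)
          }, numeric(1))
          utils::write.csv(qs, file.path(dsDir, "maxdist_summary.csv"),
                           row.names = FALSE)
        } else if (sch@estimator == "mismatch") {
          allv <- distValues(ds$normalized)
          allv <- allv[upper.tri(allv)]
          ms <- mismatchHistogram(allv)
          writeMismatchSummary(ms, file.path(dsDir, "mismatch_full.csv"))
          utils::write.csv(gapRuns(ms), file.path(dsDir, "gaps_full.csv"),
                           row.names = FALSE)
        }
      }
      manifest$datasets[[id]] <- list(
        id = id, n = n, genSeed = genSeed, seqSeed = seqSeed,
        schedules = lapply(cfg@schedules[[id]], function(s) list(
          estimator = s@estimator, sizes = s@sizes,
          replicates = s@replicates, seed = s@seed)),
        wallSeconds = round(proc.time()[3] - t0, 2))
      summary
    }, error = function(e) {
      message(sprintf("[%s] FAILED: %s", id, conditionMessage(e)))
      manifest$datasets[[id]] <<- list(id = id, n = n, failed = TRUE,
                                       error = conditionMessage(e))
      NULL
    })
    if (is.null(res)) failures <- c(failures, id) else results[[id]] <- res
  }
  jsonlite::write_json(manifest, file.path(cfg@outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(outputDir = cfg@outputDir, datasets = results,
                 failures = failures))
}

#' Descriptive statistics of nucleotide diversity across datasets
#'
#' Assembles the study-wide diversity table: one row per dataset with its
#' full-dataset diversity beta, the per-size mean of the subsample
#' diversities (rounded to 3 decimals) and the per-size percentage of values
#' within beta +/- 0.001 (rounded to 2 decimals). Sizes a dataset's schedule
#' does not include are reported as NA.
#'
#' @param outputDir a directory written by [runStudy()].
#' @return data.frame with columns `dataset`, `beta`, then `mean_<size>` and
#'   `pct_<size>` for the union of scheduled sizes.
#' @export
summarizeTable1 <- function(outputDir) {
  ids <- list.dirs(outputDir, recursive = FALSE, full.names = FALSE)
  ids <- ids[file.exists(file.path(outputDir, ids, "band_summary.csv"))]
  if (!length(ids)) stop("no diversity results found under ", outputDir)
  per <- lapply(ids, function(id) {
    bs <- utils::read.csv(file.path(outputDir, id, "band_summary.csv"))
    ts <- utils::read.csv(file.path(outputDir, id, "treeshape.csv"))
    list(id = id, beta = ts$value[ts$stat == "beta"], bs = bs)
  })
  sizes <- sort(unique(unlist(lapply(per, function(p) p$bs$size))))
  rows <- lapply(per, function(p) {
    mu <- pct <- rep(NA_real_, length(sizes))
    j <- match(p$bs$size, sizes)
    mu[j] <- round(p$bs$mean, 3)
    pct[j] <- round(p$bs$pctInBand, 2)
    row <- data.frame(dataset = p$id, beta = round(p$beta, 3))
    row[paste0("mean_", sizes)] <- as.list(mu)
    row[paste0("pct_", sizes)] <- as.list(pct)
    row
  })
  do.call(rbind, rows)
}

#' Rebuild a study configuration from a run manifest
#'
#' Reads the `manifest.json` written by [runStudy()] and reconstructs a
#' [StudyConfig] that reruns to identical outputs (all seeds being derived
#' from the recorded root seed).
#'
#' @param path path to a manifest.json.
#' @param outputDir output directory of the rebuilt config.
#' @return a [StudyConfig].
#' @export
configFromManifest <- function(path, outputDir = "study_rerun") {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  ids <- names(man$datasets)
  ns <- vapply(man$datasets, function(d) as.integer(d$n), integer(1))
  schedules <- lapply(man$datasets, function(d) {
    lapply(d$schedules, function(s)
      subsampleSchedule(s$estimator, s$sizes, s$replicates, s$seed))
  })
  names(schedules) <- ids
  new("StudyConfig",
      datasets = data.frame(id = ids, n = unname(ns),
                            stringsAsFactors = FALSE),
      theta = man$theta, seqLength = as.integer(man$seqLength),
      divergenceCap = man$divergenceCap, schedules = schedules,
      rootSeed = as.integer(man$rootSeed), outputDir = outputDir)
}
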