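# Fixtures are built in code; nothing is read from disk.

# ((a:0.2, b:0.2):0.3, c:0.5); -- cherry at depth 0.2, root age 0.5
threeTipTree <- function() {
  ape::read.tree(text = "((a:0.2,b:0.2):0.3,c:0.5);")
}

# two-tip ultrametric tree with tip branches of length t
twoTipTree <- function(t) {
  ape::read.tree(text = sprintf("(a:%.10f,b:%.10f);", t, t))
}

# maximally balanced rooted binary tree on n tips (recursive ceil/floor
# halving), unit branch lengths
balancedTree <- function(n) {
  build <- function(k, prefix) {
    if (k == 1L) return(sprintf("%s:1", prefix))
    left <- ceiling(k / 2)
    sprintf("(%s,%s):1",
            build(left, paste0(prefix, "L")),
            build(k - left, paste0(prefix, "R")))
  }
  ape::read.tree(text = paste0(build(n, "t"), ";"))
}

caterpillarTree <- function(n) {
  ape::stree(n, type = "left")
}

# alignment whose p-distance structure is known exactly: s1 == s2,
# s3 differs from both at `k` of `L` sites
toyAlignment <- function(L = 1500L, k = 15L) {
  base <- paste(rep("A", L), collapse = "")
  mutated <- c(rep("T", k), rep("A", L - k))
  Biostrings::DNAStringSet(c(
    s1 = base, s2 = base, s3 = paste(mutated, collapse = "")))
}

# JCDistanceMatrix directly from a symmetric matrix of values
toyMatrix <- function(v, labels = paste0("s", seq_len(nrow(v)))) {
  dimnames(v) <- list(labels, labels)
  new("JCDistanceMatrix", values = v, scaleTag = "jc_raw")
}

# ResampleResult built by hand (for summary-function unit tests)
toyResult <- function(values, sizes, estimator = "diversity") {
  colnames(values) <- sizes
  new("ResampleResult", estimator = estimator, sizes = as.integer(sizes),
      values = values, datasetId = "toy", seed = 0L)
}

# a small simulated dataset shared across tests (memoised; fixed seeds)
.datasetCache <- new.env(parent = emptyenv())
cachedDataset <- function(n = 60L, genSeed = 401L, seqSeed = 402L) {
  key <- paste0("d", n, "_", genSeed)
  if (is.null(.datasetCache[[key]])) {
    g <- simulateGenealogy(n, seed = genSeed)
    res <- enforceDivergenceCap(g, L = 1500L, cap = 0.03, seed = seqSeed)
    res$normalized <- minmaxNormalize(res$matrix)
    res$raw <- res$matrix
    res$genealogy <- g
    .datasetCache[[key]] <- res
  }
  .datasetCache[[key]]
}
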