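#' Simulate a constant-size Kingman coalescent genealogy
#'
#' Generates a random genealogy of `nTips` haploid lineages sampled from a
#' single panmictic population of constant size. With j active lineages the
#' waiting time to the next coalescence is Exponential with rate j(j-1)/2,
#' in units of 2N generations; the merging pair is chosen uniformly at
#' random among unordered pairs. The result is a rooted, binary, ultrametric
#' `ape::phylo` tree with tip labels `"t1" ... "tn"`.
#'
#' @param nTips number of sampled lineages (>= 2).
#' @param seed optional integer; if given the simulation is reproducible and
#'   the session RNG is left untouched.
#' @return an object of class `phylo`.
#' @examples
#' g <- simulateGenealogy(10, seed = 1)
#' tmrca(g)
#' @export
simulateGenealogy <- function(nTips, seed = NULL) {
  if (!is.numeric(nTips) || length(nTips) != 1L || nTips < 2 ||
      nTips != round(nTips))
    stop("'nTips' must be a single integer >= 2")
  nTips <- as.integer(nTips)
  withSeed(seed, {
    nEdge <- 2L * nTips - 2L
    edge <- matrix(0L, nEdge, 2L)
    edgeLen <- numeric(nEdge)
    heights <- numeric(2L * nTips - 1L)
    active <- seq_len(nTips)
    # first coalescence gets the highest internal id, the root ends at nTips+1
    nextNode <- 2L * nTips - 1L
    t <- 0
    row <- 0L
    k <- nTips
    while (k >= 2L) {
      t <- t + stats::rexp(1L, rate = k * (k - 1) / 2)
      pair <- sample.int(k, 2L)
      kids <- active[pair]
      heights[nextNode] <- t
      edge[row + 1L, ] <- c(nextNode, kids[1L])
      edge[row + 2L, ] <- c(nextNode, kids[2L])
      edgeLen[row + 1L] <- t - heights[kids[1L]]
      edgeLen[row + 2L] <- t - heights[kids[2L]]
      row <- row + 2L
      active <- c(active[-pair], nextNode)
      nextNode <- nextNode - 1L
      k <- k - 1L
    }
    phy <- structure(list(
      edge = edge,
      edge.length = edgeLen,
      tip.label = paste0("t", seq_len(nTips)),
      Nnode = nTips - 1L
    ), class = "phylo")
    ape::reorder.phylo(phy, "cladewise")
  })
}

#' Time to the most recent common ancestor
#'
#' Root age of a rooted ultrametric genealogy: the root-to-tip path length
#' (all tips being equidistant from the root).
#'
#' @param g a rooted `phylo` tree.
#' @return root age in the tree's branch-length units.
#' @export
tmrca <- function(g) {
  stopifnot(inherits(g, "phylo"))
  depths <- ape::node.depth.edgelength(g)
  max(depths[seq_len(ape::Ntip(g))])
}

#' Tree diameter
#'
#' Maximum tip-to-tip path length. For an ultrametric tree this equals twice
#' the root age, but the computation is general (dynamic program over the
#' two deepest tip paths entering each node), so it stays correct for any
#' rescaled branch lengths.
#'
#' @param g a rooted `phylo` tree.
#' @return the maximum path length between two tips.
#' @export
treeDiameter <- function(g) {
  stopifnot(inherits(g, "phylo"))
  nTip <- ape::Ntip(g)
  nNode <- nTip + g$Nnode
  # deepest tip distance below each node, filled tips-first in postorder
  down <- numeric(nNode)
  po <- ape::reorder.phylo(g, "postorder")
  # per-parent best two child depths
  top1 <- numeric(nNode)
  top2 <- numeric(nNode)
  seen <- integer(nNode)
  for (i in seq_len(nrow(po$edge))) {
    par <- po$edge[i, 1L]
    ch <- po$edge[i, 2L]
    d <- down[ch] + po$edge.length[i]
    seen[par] <- seen[par] + 1L
    if (d > top1[par]) {
      top2[par] <- top1[par]
      top1[par] <- d
    } else if (d > top2[par]) top2[par] <- d
    down[par] <- top1[par]
  }
  internal <- which(seen > 0L)
  max(top1[internal] + top2[internal])
}

#' Colless imbalance index
#'
#' Sum over internal nodes of the absolute difference between the tip counts
#' of the two daughter clades. The normalized form divides by the caterpillar
#' maximum (n-1)(n-2)/2, mapping the index into \[0, 1\].
#'
#' @param g a rooted, binary `phylo` tree.
#' @param normalized if TRUE return the normalized index (requires >= 3 tips).
#' @return the (normalized) Colless index.
#' @examples
#' colless <- collessIndex(simulateGenealogy(500, seed = 1), normalized = TRUE)
#' @export
collessIndex <- function(g, normalized = FALSE) {
  stopifnot(inherits(g, "phylo"))
  n <- ape::Ntip(g)
  if (normalized && n < 3L)
    stop("the normalized Colless index requires at least 3 tips")
  counts <- nodeTipCounts(g)
  kids <- childList(g)
  internal <- which(lengths(kids) > 0L)
  if (any(lengths(kids[internal]) != 2L))
    stop("Colless index requires a strictly binary tree")
  imb <- vapply(internal, function(nd) {
    abs(counts[kids[[nd]][1L]] - counts[kids[[nd]][2L]])
  }, numeric(1))
  total <- sum(imb)
  if (normalized) total / ((n - 1) * (n - 2) / 2) else total
}

#' Aldous split profile near the root
#'
#' Follows a greedy path from the root that always descends into the larger
#' daughter clade (ties resolved toward the first child) and records, for
#' each of the first `k` internal nodes on that path, the tip count of its
#' larger daughter. A balanced topology yields the iterated ceil-halving
#' profile; highly imbalanced genealogies stay near n-1 for several steps.
#'
#' @param g a rooted binary `phylo` tree.
#' @param k number of internal nodes to report, at most `nTips - 1`.
#' @return data.frame with columns `nodeRank` (1..k from the root) and
#'   `largerDaughterSize`. If the greedy path runs out of internal nodes the
#'   profile is truncated with a warning.
#' @export
aldousSplitProfile <- function(g, k) {
  stopifnot(inherits(g, "phylo"))
  n <- ape::Ntip(g)
  if (k < 1 || k > n - 1) stop("'k' must be between 1 and nTips - 1")
  counts <- nodeTipCounts(g)
  kids <- childList(g)
  node <- n + 1L  # root
  rank <- integer(0)
  size <- integer(0)
  for (i in seq_len(k)) {
    ch <- kids[[node]]
    if (length(ch) == 0L) {
      warning(sprintf(
        "greedy path reached a tip after %d internal nodes; profile truncated",
        i - 1L))
      break
    }
    sizes <- counts[ch]
    larger <- ch[which.max(sizes)]  # which.max takes the first child on ties
    rank <- c(rank, i)
    size <- c(size, counts[larger])
    node <- larger
  }
  data.frame(nodeRank = rank, largerDaughterSize = size)
}

# tips below each node (tips count themselves as 1)
nodeTipCounts <- function(g) {
  nTip <- ape::Ntip(g)
  counts <- integer(nTip + g$Nnode)
  counts[seq_len(nTip)] <- 1L
  po <- ape::reorder.phylo(g, "postorder")
  for (i in seq_len(nrow(po$edge)))
    counts[po$edge[i, 1L]] <- counts[po$edge[i, 1L]] + counts[po$edge[i, 2L]]
  counts
}

# children of each node, in edge-matrix order
childList <- function(g) {
  nNode <- ape::Ntip(g) + g$Nnode
  kids <- vector("list", nNode)
  for (i in seq_len(nNode)) kids[[i]] <- integer(0)
  for (i in seq_len(nrow(g$edge))) {
    par <- g$edge[i, 1L]
    kids[[par]] <- c(kids[[par]], g$edge[i, 2L])
  }
  kids
}
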