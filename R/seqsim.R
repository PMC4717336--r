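BASES <- c("A", "C", "G", "T")

#' Rescale genealogy branch lengths to a target diameter
#'
#' Multiplies every branch by `targetDiameter / treeDiameter(g)`, converting
#' coalescent time units into expected substitutions per site while
#' preserving the topology, relative branch lengths and ultrametricity. The
#' returned tree's maximum tip-to-tip path length equals `targetDiameter`,
#' i.e. the maximum expected pairwise divergence.
#'
#' @param g a `phylo` genealogy with positive diameter.
#' @param targetDiameter desired maximum tip-to-tip path length (> 0),
#'   in expected substitutions/site.
#' @return the rescaled `phylo` tree.
#' @export
rescaleBranches <- function(g, targetDiameter) {
  stopifnot(inherits(g, "phylo"))
  if (!is.numeric(targetDiameter) || targetDiameter <= 0)
    stop("'targetDiameter' must be > 0")
  d <- treeDiameter(g)
  if (d <= 0) stop("cannot rescale a zero-diameter tree")
  g$edge.length <- g$edge.length * (targetDiameter / d)
  g
}

#' Evolve sequences along a genealogy under the Jukes-Cantor model
#'
#' Simulates nucleotide sequences of length `L` down the tree. The root
#' sequence is drawn i.i.d. uniform over A/C/G/T (the JC stationary
#' distribution); along a branch of length t (expected substitutions/site)
#' each site independently changes with the exact JC transition probability
#' p(t) = (3/4)(1 - exp(-4t/3)), to one of the three other bases chosen
#' uniformly. Sampling the closed-form branch transition directly is
#' distributionally identical to simulating the substitution process
#' event-by-event, and much faster.
#'
#' @param g a `phylo` tree with branch lengths in expected substitutions/site.
#' @param L sequence length in bp (default 1500).
#' @param seed optional integer seed for reproducibility.
#' @return a [Biostrings::DNAStringSet] of the tip sequences, named by tip
#'   label, with the seed recorded in its metadata.
#' @examples
#' g <- rescaleBranches(simulateGenealogy(5, seed = 1), 0.025)
#' aln <- evolveJC(g, L = 1500, seed = 2)
#' @export
evolveJC <- function(g, L = 1500L, seed = NULL) {
  stopifnot(inherits(g, "phylo"))
  if (any(g$edge.length < 0)) stop("negative branch lengths are not allowed")
  if (L < 1) stop("'L' must be >= 1")
  L <- as.integer(L)
  nTip <- ape::Ntip(g)
  withSeed(seed, {
    po <- ape::reorder.phylo(g, "cladewise")  # parents precede children
    seqs <- matrix(0L, nrow = nTip + g$Nnode, ncol = L)
    seqs[nTip + 1L, ] <- sample.int(4L, L, replace = TRUE)
    pchange <- 0.75 * (1 - exp(-4 * po$edge.length / 3))
    for (i in seq_len(nrow(po$edge))) {
      par <- po$edge[i, 1L]
      ch <- po$edge[i, 2L]
      s <- seqs[par, ]
      hit <- which(stats::runif(L) < pchange[i])
      if (length(hit)) {
        shift <- sample.int(3L, length(hit), replace = TRUE)
        s[hit] <- (s[hit] - 1L + shift) %% 4L + 1L
      }
      seqs[ch, ] <- s
    }
    tipChars <- matrix(BASES[seqs[seq_len(nTip), , drop = FALSE]], nrow = nTip)
    aln <- Biostrings::DNAStringSet(apply(tipChars, 1L, paste0, collapse = ""))
    names(aln) <- g$tip.label
    S4Vectors::metadata(aln) <- list(seed = seed, L = L)
    aln
  })
}

#' Rescale and evolve under a realized-divergence cap
#'
#' Emulates case-by-case branch-length rescaling that keeps intraspecific
#' divergence below a cap: the genealogy is first rescaled to a diameter of
#' `0.85 * cap`, sequences are evolved under JC, and while the realized
#' maximum pairwise JC distance reaches the cap the scale is shrunk by a
#' factor 0.9 and the sequences re-evolved with the same seed. The first
#' accepted pair (tree, alignment) is returned, guaranteeing that every
#' generated dataset satisfies max pairwise JC distance < `cap`.
#'
#' @param g a `phylo` genealogy in coalescent units.
#' @param L sequence length in bp.
#' @param cap realized divergence cap (default 0.03, i.e. 3%).
#' @param seed optional integer seed (reused across shrink iterations so the
#'   mutational history shrinks coherently with the tree).
#' @param maxIter shrink iterations before giving up (default 20).
#' @return a list with elements `tree` (rescaled `phylo`), `alignment`
#'   (`DNAStringSet`), `matrix` (the accepted [JCDistanceMatrix]), and
#'   `scale` (final diameter as a fraction of `cap`).
#' @export
enforceDivergenceCap <- function(g, L = 1500L, cap = 0.03, seed = NULL,
                                 maxIter = 20L) {
  if (cap <= 0) stop("'cap' must be > 0")
  target <- 0.85 * cap
  scaled <- rescaleBranches(g, target)
  for (i in seq_len(maxIter)) {
    aln <- evolveJC(scaled, L = L, seed = seed)
    m <- pairwiseMatrix(aln)
    mx <- max(distValues(m))
    if (mx < cap) {
      md <- S4Vectors::metadata(aln)
      md$scale <- target / cap
      S4Vectors::metadata(aln) <- md
      return(list(tree = scaled, alignment = aln, matrix = m,
                  scale = target / cap))
    }
    target <- target * 0.9
    scaled$edge.length <- scaled$edge.length * 0.9
  }
  stop(sprintf(
    "failed to satisfy the %.3g divergence cap after %d shrink iterations",
    cap, maxIter))
}

#' Infinite-sites mutation overlay on a coalescent genealogy
#'
#' Drops mutations on the genealogy in its coalescent time units: each
#' branch of length t receives Poisson(theta/2 * t) mutations, every
#' mutation hits a new site (infinite-sites assumption), and the number of
#' pairwise differences between two tips is the number of mutations on the
#' path connecting them. With time in units of 2N generations and rate
#' theta/2 per lineage, the expected number of pairwise differences equals
#' theta = 4 N mu. Used to validate the simulated genealogies against
#' coalescent theory; the finite-sites sequences themselves are generated by
#' [evolveJC()] after rescaling.
#'
#' @param g a `phylo` genealogy in coalescent units.
#' @param theta population mutation parameter (>= 0).
#' @param seed optional integer seed.
#' @return a list with `theta`, `pairwiseDifferences` (symmetric integer
#'   matrix over tips), and `segregatingSites` (total mutation count).
#' @examples
#' ov <- overlayInfiniteSites(simulateGenealogy(2, seed = 1), theta = 3)
#' ov$pairwiseDifferences
#' @export
overlayInfiniteSites <- function(g, theta, seed = NULL) {
  stopifnot(inherits(g, "phylo"))
  if (theta < 0) stop("'theta' must be >= 0")
  nTip <- ape::Ntip(g)
  withSeed(seed, {
    muts <- stats::rpois(nrow(g$edge), lambda = theta / 2 * g$edge.length)
    # indicator of which tips descend from each edge
    po <- ape::reorder.phylo(g, "postorder")
    mutsPo <- muts[match(paste(po$edge[, 1], po$edge[, 2]),
                         paste(g$edge[, 1], g$edge[, 2]))]
    nNode <- nTip + g$Nnode
    below <- matrix(FALSE, nNode, nTip)
    below[cbind(seq_len(nTip), seq_len(nTip))] <- TRUE
    D <- matrix(0L, nTip, nTip)
    for (i in seq_len(nrow(po$edge))) {
      par <- po$edge[i, 1L]
      ch <- po$edge[i, 2L]
      if (mutsPo[i] > 0L) {
        inSet <- below[ch, ]
        # each mutation separates descendants of this edge from the rest
        D[inSet, !inSet] <- D[inSet, !inSet] + mutsPo[i]
        D[!inSet, inSet] <- D[!inSet, inSet] + mutsPo[i]
      }
      below[par, ] <- below[par, ] | below[ch, ]
    }
    dimnames(D) <- list(g$tip.label, g$tip.label)
    list(theta = theta, pairwiseDifferences = D,
         segregatingSites = sum(muts))
  })
}
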