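test_that("branch rescaling hits the target diameter and preserves shape", {
  g <- simulateGenealogy(12, seed = 21L)
  same <- rescaleBranches(g, treeDiameter(g))
  expect_equal(same$edge.length, g$edge.length, tolerance = 1e-12)
  tr2 <- twoTipTree(1.0)  # diameter 2.0
  sc <- rescaleBranches(tr2, 0.03)
  expect_equal(sc$edge.length, c(0.015, 0.015))
  sc2 <- rescaleBranches(g, 0.03)
  expect_equal(treeDiameter(sc2), 0.03, tolerance = 1e-12)
  depths <- ape::node.depth.edgelength(sc2)[1:12]
  expect_lt(diff(range(depths)), 1e-12)  # still ultrametric
  zero <- g
  zero$edge.length[] <- 0
  expect_error(rescaleBranches(zero, 0.03), "zero-diameter")
  expect_error(rescaleBranches(g, -1), "targetDiameter")
})

test_that("JC evolution is exact per branch and reproducible", {
  g <- simulateGenealogy(6, seed = 22L)
  zero <- g
  zero$edge.length[] <- 0
  aln0 <- evolveJC(zero, L = 200L, seed = 1L)
  expect_length(unique(as.character(aln0)), 1L)  # no time, no change
  # byte-identical under identical seeds
  sc <- rescaleBranches(g, 0.03)
  expect_identical(as.character(evolveJC(sc, 500L, seed = 9L)),
                   as.character(evolveJC(sc, 500L, seed = 9L)))
  neg <- sc
  neg$edge.length[1] <- -0.01
  expect_error(evolveJC(neg, 100L), "negative")

  # mean mismatch proportion at path length t = 0.03 equals
  # (3/4)(1 - exp(-0.04)) = 0.0294080
  tr <- twoTipTree(0.015)
  withr::with_seed(23L, {
    p <- replicate(2000, {
      a <- as.character(evolveJC(tr, 1500L))
      mean(strsplit(a[1], "")[[1]] != strsplit(a[2], "")[[1]])
    })
  })
  expect_lt(abs(mean(p) - 0.75 * (1 - exp(-0.04))),
            3 * sd(p) / sqrt(length(p)))
  # saturation: a very long branch approaches 3/4 mismatches
  long <- twoTipTree(25)
  a <- as.character(evolveJC(long, 20000L, seed = 24L))
  psat <- mean(strsplit(a[1], "")[[1]] != strsplit(a[2], "")[[1]])
  expect_equal(psat, 0.75, tolerance = 0.02)
})

test_that("site mismatch counts are Binomial(L, p(t)) and distances converge", {
  L <- 500L
  t <- 0.1
  pexp <- 0.75 * (1 - exp(-4 * t / 3))
  tr <- twoTipTree(t / 2)
  withr::with_seed(25L, {
    counts <- replicate(1000, {
      a <- as.character(evolveJC(tr, L))
      sum(strsplit(a[1], "")[[1]] != strsplit(a[2], "")[[1]])
    })
  })
  # chi-square GOF against the binomial, pooling tails to expected >= 5
  ks <- 0:L
  pr <- stats::dbinom(ks, L, pexp)
  lo <- min(which(cumsum(pr) > 5 / 1000))
  hi <- max(which(rev(cumsum(rev(pr))) > 5 / 1000))
  breaks <- c(-Inf, seq(lo, hi), Inf)
  obs <- table(cut(counts, breaks))
  expc <- vapply(seq_along(obs), function(i) {
    stats::pbinom(breaks[i + 1], L, pexp) - stats::pbinom(breaks[i], L, pexp)
  }, numeric(1)) * 1000
  chi <- sum((as.numeric(obs) - expc)^2 / expc)
  pval <- stats::pchisq(chi, df = length(obs) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)

  # realized JC distance converges to the path length at large L
  big <- evolveJC(twoTipTree(0.01), 150000L, seed = 26L)
  d <- distValues(pairwiseMatrix(big))[1, 2]
  expect_lt(abs(d - 0.02) / 0.02, 0.05)
})

test_that("JC simulator agrees with an independent sequence simulator", {
  skip_if_not_installed("phangorn")
  tr <- twoTipTree(0.05)
  withr::with_seed(27L, {
    mine <- replicate(400, {
      a <- as.character(evolveJC(tr, 1000L))
      sum(strsplit(a[1], "")[[1]] != strsplit(a[2], "")[[1]])
    })
    ref <- replicate(400, {
      m <- as.character(phangorn::simSeq(tr, l = 1000))
      sum(m[1, ] != m[2, ])
    })
  })
  expect_gt(suppressWarnings(stats::ks.test(mine, ref)$p.value), 0.01)
})

test_that("the divergence cap is enforced on realized JC distances", {
  g <- simulateGenealogy(40, seed = 28L)
  res <- enforceDivergenceCap(g, L = 1500L, cap = 0.03, seed = 29L)
  expect_lt(max(distValues(res$matrix)), 0.03)
  expect_lte(treeDiameter(res$tree), 0.85 * 0.03 + 1e-12)
  # deterministic given seeds
  res2 <- enforceDivergenceCap(g, L = 1500L, cap = 0.03, seed = 29L)
  expect_identical(as.character(res$alignment), as.character(res2$alignment))
  # a tree entering with a larger diameter leaves strictly smaller
  wide <- rescaleBranches(g, 0.1)
  res3 <- enforceDivergenceCap(wide, L = 1500L, cap = 0.03, seed = 30L)
  expect_lt(treeDiameter(res3$tree), 0.1)
  expect_error(enforceDivergenceCap(g, cap = -1), "cap")
})

test_that("the infinite-sites overlay matches coalescent expectations", {
  g <- simulateGenealogy(8, seed = 31L)
  ov0 <- overlayInfiniteSites(g, theta = 0, seed = 1L)
  expect_equal(ov0$segregatingSites, 0L)
  expect_true(all(ov0$pairwiseDifferences == 0))

  withr::with_seed(32L, {
    # E[pairwise differences] = theta at n = 2
    diffs <- replicate(10000, {
      overlayInfiniteSites(simulateGenealogy(2), theta = 3)$pairwiseDifferences[1, 2]
    })
    expect_lt(abs(mean(diffs) - 3), 3 * sd(diffs) / sqrt(length(diffs)))
    # E[segregating sites] = theta * sum_{i<n} 1/i = 8.48690 at n = 10;
    # and total mutations average theta/2 * total branch length
    trees <- replicate(5000, simulateGenealogy(10), simplify = FALSE)
    segs <- vapply(trees, function(tr)
      overlayInfiniteSites(tr, theta = 3)$segregatingSites, numeric(1))
    expect_lt(abs(mean(segs) - 3 * sum(1 / (1:9))),
              3 * sd(segs) / sqrt(length(segs)))
    tot <- vapply(trees, function(tr) sum(tr$edge.length), numeric(1))
    expect_lt(abs(mean(segs) - 1.5 * mean(tot)), 3 * sd(segs) / sqrt(5000))
  })

  # pairwise differences are symmetric, zero-diagonal, and bounded by S
  ov <- overlayInfiniteSites(g, theta = 5, seed = 33L)
  D <- ov$pairwiseDifferences
  expect_identical(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_lte(max(D), ov$segregatingSites)
})
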