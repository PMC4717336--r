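test_that("subsamples are uniform draws without replacement", {
  withr::with_seed(71L, {
    for (i in 1:50) {
      idx <- drawSubsample(20, 7)
      expect_length(idx, 7L)
      expect_false(anyDuplicated(idx) > 0)
      expect_true(all(idx >= 1 & idx <= 20))
    }
    expect_setequal(drawSubsample(6, 6), 1:6)
    # inclusion probability of each index is s/n = 2/5
    draws <- replicate(20000, drawSubsample(5, 2))
    freq <- tabulate(draws, 5) / 20000
    expect_true(all(abs(freq - 0.4) < 0.015))
  })
  expect_error(drawSubsample(5, 6), "size")
  expect_error(drawSubsample(5, 1), "size")
})

test_that("schedules produce complete reproducible grids", {
  ds <- cachedDataset()
  sch <- subsampleSchedule("diversity", c(2, 5, 10), 50, seed = 72L)
  r <- runSchedule(m = ds$normalized, sched = sch, datasetId = "toy")
  expect_s4_class(r, "ResampleResult")
  expect_equal(dim(resampleValues(r)), c(50L, 3L))
  expect_false(anyNA(resampleValues(r)))
  r2 <- runSchedule(m = ds$normalized, sched = sch)
  expect_identical(resampleValues(r), resampleValues(r2))
  # a size equal to n always returns the full-dataset estimator
  schN <- subsampleSchedule("diversity", c(5, 60), 10, seed = 73L)
  rN <- runSchedule(m = ds$normalized, sched = schN)
  expect_true(all(resampleValues(rN)[, "60"] ==
                  nucleotideDiversity(ds$normalized)))
  # configuration errors
  expect_error(runSchedule(m = ds$normalized,
                           sched = subsampleSchedule("haplotypes", 5, 2)),
               "alignment")
  expect_error(runSchedule(aln = ds$alignment,
                           sched = subsampleSchedule("diversity", 5, 2)),
               "distance matrix")
  expect_error(runSchedule(m = ds$normalized,
                           sched = subsampleSchedule("diversity", c(2, 500), 2)),
               "exceed")
})

test_that("Monte-Carlo subsampling matches exhaustive enumeration", {
  # n = 6 toy matrix: the MC distribution over subsets must match the
  # uniform distribution over all C(6, s) subsets (chi-square GOF)
  v <- matrix(0, 6, 6)
  v[upper.tri(v)] <- seq(0.002, 0.03, length.out = 15)
  m <- toyMatrix(v + t(v))
  for (s in c(2L, 3L)) {
    exact <- apply(utils::combn(6, s), 2, function(i) nucleotideDiversity(m, i))
    sch <- subsampleSchedule("diversity", s, 6000L, seed = 74L)
    mc <- as.vector(resampleValues(runSchedule(m = m, sched = sch)))
    key <- signif(exact, 10)
    expect_setequal(unique(signif(mc, 10)), unique(key))
    obs <- table(factor(signif(mc, 10), levels = sort(unique(key))))
    expc <- table(factor(key, levels = sort(unique(key)))) / length(key) * 6000
    chi <- sum((as.numeric(obs) - as.numeric(expc))^2 / as.numeric(expc))
    pval <- stats::pchisq(chi, df = length(expc) - 1, lower.tail = FALSE)
    expect_gt(pval, 0.01)
  }
})

test_that("band summaries count values in the closed beta band", {
  beta <- 0.015
  vals <- cbind(rep(beta, 10), c(rep(beta, 5), rep(beta + 0.002, 5)))
  r <- toyResult(vals, c(5, 10))
  bs <- bandSummary(r, beta)
  expect_equal(bs$pctInBand, c(100, 50))
  expect_equal(bs$mean[1], beta)
  # band is closed: values exactly at beta +/- halfWidth are inside
  # (integer-exact arithmetic so the boundary is hit exactly)
  r2 <- toyResult(cbind(c(3, 1, 5)), 5)
  expect_equal(bandSummary(r2, beta = 2, halfWidth = 1)$pctInBand, 200 / 3)
  expect_equal(bandSummary(r2, beta = 3, halfWidth = 2)$pctInBand, 100)
})

test_that("CLT diagnostics report shrinking spread with sample size", {
  const <- toyResult(cbind(rep(0.01, 20)), 5)
  cd <- cltDiagnostics(const)
  expect_equal(cd$variance, 0)
  expect_equal(cd$skewness, 0)
  expect_true(cd$degenerate)
  withr::with_seed(75L, {
    z <- stats::rnorm(5000)
    rz <- toyResult(cbind(z), 5)
    expect_lt(abs(cltDiagnostics(rz)$skewness), 0.1)
    ds <- cachedDataset()
    sch <- subsampleSchedule("diversity", c(5, 30), 400, seed = 76L)
    r <- runSchedule(m = ds$normalized, sched = sch)
    cd2 <- cltDiagnostics(r, beta = nucleotideDiversity(ds$normalized))
    expect_lt(cd2$variance[cd2$size == 30], cd2$variance[cd2$size == 5])
  })
})

test_that("quartile summaries match direct sort-based computation", {
  r <- toyResult(cbind(c(1, 2, 3, 4)), 5, estimator = "haplotypes")
  qs <- quartileSummary(r)
  expect_equal(qs$median, 2.5)
  expect_equal(qs$min, 1)
  expect_equal(qs$max, 4)
  expect_equal(qs$q1, 1.75)  # linear interpolation
  expect_equal(qs$q3, 3.25)
  same <- toyResult(cbind(rep(7, 9)), 5, estimator = "haplotypes")
  expect_equal(unlist(quartileSummary(same)[, -1]), rep(7, 5),
               ignore_attr = TRUE)
  withr::with_seed(77L, {
    x <- stats::rpois(101, 12)
    rx <- toyResult(cbind(x), 5, estimator = "haplotypes")
    q <- quartileSummary(rx)
    sorted <- sort(x)
    expect_equal(q$median, sorted[51])
    expect_equal(q$min, sorted[1])
    expect_equal(q$max, sorted[101])
  })
})

test_that("Michaelis-Menten fitting recovers exact and limiting curves", {
  sizes <- c(2, seq(10, 150, 10))
  exact <- 2.0 * sizes / (1 + 0.05 * sizes)
  fit <- fitMichaelisMenten(sizes, exact)
  expect_equal(unname(mmConstants(fit)["a"]), 2.0, tolerance = 1e-6)
  expect_equal(unname(mmConstants(fit)["b"]), 0.05, tolerance = 1e-6)
  expect_equal(fit@residualVariance, 0, tolerance = 1e-10)
  # horizontal data: asymptote-dominated fit with a/b near the constant
  flat <- fitMichaelisMenten(sizes, rep(12, length(sizes)))
  expect_equal(flat@a / flat@b, 12, tolerance = 0.05)
  expect_error(fitMichaelisMenten(c(2, 10), c(1, 2)), "3 points")
  expect_error(fitMichaelisMenten(c(-1, 2, 3), c(1, 2, 3)), "positive")
})

test_that("the Michaelis-Menten slope is analytic and decreasing", {
  fit <- new("MMFit", a = 2.0, b = 0.05, residualVariance = 0,
             nPoints = 16L, sizes = 1, medians = 1)
  expect_equal(mmSlope(fit, 0), 2.0)
  expect_equal(mmSlope(fit, 20), 0.5)  # 2/(1 + 1)^2
  # central finite difference oracle
  h <- 1e-6
  f <- function(x) fit@a * x / (1 + fit@b * x)
  for (x in c(1, 10, 50, 140)) {
    expect_equal(mmSlope(fit, x), (f(x + h) - f(x - h)) / (2 * h),
                 tolerance = 1e-8)
  }
  xs <- seq(0, 150, 5)
  sl <- mmSlope(fit, xs)
  expect_true(all(sl > 0))
  expect_true(all(diff(sl) < 0))
})

test_that("haplotype medians and max-distance recovery rise with sample size", {
  ds <- cachedDataset()
  hs <- subsampleSchedule("haplotypes", c(2, 5, 10, 20, 40, 60), 100,
                          seed = 78L)
  hr <- runSchedule(aln = ds$alignment, sched = hs)
  med <- quartileSummary(hr)$median
  expect_true(all(diff(med) >= 0))
  expect_true(all(resampleValues(hr) <=
                  matrix(sampleSizes(hr), 100, 6, byrow = TRUE)))
  mdSch <- subsampleSchedule("maxdist", c(2, 5, 10, 20, 40, 60), 400,
                             seed = 79L)
  mr <- runSchedule(m = ds$normalized, sched = mdSch)
  full <- maxPairwise(ds$normalized)
  pHit <- colMeans(resampleValues(mr) >= full - 1e-12)
  expect_true(all(diff(pHit) >= 0))
  expect_equal(unname(pHit[6]), 1)  # size n recovers the maximum surely
})
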