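test_that("buildHistogram bins by hand-checkable rules", {
  h <- buildHistogram(c(-100, -100, 0), nBins = 2, range = c(-200, 100))
  expect_equal(binCounts(h), c(2, 1))
  expect_equal(binEdges(h), c(-200, -50, 100))

  # constant input lands in a single bin; out-of-range values are clipped
  h2 <- buildHistogram(rep(-90, 7), nBins = 4, range = c(-200, 100))
  expect_equal(sum(binCounts(h2)), 7)
  expect_equal(sum(binCounts(h2) > 0), 1)
  h3 <- buildHistogram(c(-500, 500), nBins = 3, range = c(-200, 100))
  expect_equal(binCounts(h3), c(1, 0, 1))

  expect_error(buildHistogram(numeric(0), 4, c(-200, 100)), "no values")
})

test_that("normalized correlation matches its closed-form endpoints", {
  h <- buildHistogram(c(-100, -100, 0), nBins = 2, range = c(-200, 100))
  expect_equal(normalizedCorrelation(h, h), 1, tolerance = 1e-12)

  up <- new("DensityHistogram", binEdges = c(0, 1, 2), counts = c(1, 0))
  dn <- new("DensityHistogram", binEdges = c(0, 1, 2), counts = c(0, 1))
  expect_equal(normalizedCorrelation(up, dn), -1, tolerance = 1e-12)

  flat <- new("DensityHistogram", binEdges = c(0, 1, 2), counts = c(2, 2))
  expect_error(normalizedCorrelation(flat, up), "zero-variance")
  misaligned <- new("DensityHistogram", binEdges = c(0, 2, 4),
                    counts = c(1, 0))
  expect_error(normalizedCorrelation(up, misaligned), "bin edges")
})

test_that("correlation is symmetric, bounded, and scale invariant", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(2:32, 1)
    e <- seq(-200, 100, length.out = n + 1)
    h1 <- new("DensityHistogram", binEdges = e, counts = runif(n, 0, 50))
    h2 <- new("DensityHistogram", binEdges = e, counts = runif(n, 0, 50))
    r <- normalizedCorrelation(h1, h2)
    expect_lte(abs(r), 1 + 1e-12)
    expect_equal(normalizedCorrelation(h2, h1), r, tolerance = 1e-12)
    # positive affine rescaling of counts leaves r unchanged
    h3 <- new("DensityHistogram", binEdges = e,
              counts = 3.7 * h1@counts + 11)
    expect_equal(normalizedCorrelation(h3, h2), r, tolerance = 1e-12)
  }
})

test_that("prior dissimilarity spans [0, 2] with 0 at self", {
  h <- buildHistogram(rnorm(500, -100, 15), nBins = 16, range = c(-200, 100))
  expect_identical(priorDissimilarity(h, h), 1 - normalizedCorrelation(h, h))
  expect_lt(priorDissimilarity(h, h), 1e-12)
  up <- new("DensityHistogram", binEdges = c(0, 1, 2), counts = c(1, 0))
  dn <- new("DensityHistogram", binEdges = c(0, 1, 2), counts = c(0, 1))
  expect_equal(priorDissimilarity(up, dn), 2, tolerance = 1e-12)
})

test_that("dissimilarity grows with the edema fraction of a region", {
  prior <- suitePrior()
  ph <- prior@histogram
  n <- 20000
  vals <- withr::with_seed(7, {
    ad <- rnorm(n, prior@adiposeMean, prior@adiposeStd)
    ed <- qnorm(runif(n, pnorm(-50, 0, 15), pnorm(50, 0, 15)), 0, 15)
    list(ad = ad, ed = ed)
  })
  mix <- function(frac) {
    k <- round(frac * n)
    v <- c(vals$ad[seq_len(n - k)], vals$ed[seq_len(k)])
    priorDissimilarity(buildHistogram(v), ph)
  }
  d <- vapply(c(0, 0.25, 0.5), mix, numeric(1))
  expect_true(all(diff(d) > 0))
  expect_lt(d[1], 0.05)
})

test_that("fitPrior recovers the moments of the generating model", {
  pairs <- generateTrainingPairs(phantomSpec(), n = 5, seed = 101)
  prior <- fitPrior(pairs)
  pooled <- sum(vapply(pairs, function(p) sum(pixelValues(p[[1]])),
                       numeric(1)))
  expect_gt(pooled, 1e4)
  expect_lt(abs(prior@adiposeMean - (-100)), 1)
  # noise adds in quadrature: sd ~ sqrt(15^2 + 5^2)
  expect_lt(abs(prior@adiposeStd - sqrt(15^2 + 5^2)), 1)
  expect_length(binCounts(prior@histogram), 64)

  const <- applyMask(densityImage(matrix(-90, 4, 4)),
                     binaryMask(matrix(1, 4, 4)))
  expect_error(fitPrior(list(list(binaryMask(matrix(1, 4, 4)), const))),
               "degenerate std")
  expect_error(fitPrior(list()), "at least one")
})

test_that("the surrogate prior generator fills the support from the model", {
  prior <- new("PriorModel", adiposeMean = -100, adiposeStd = 15,
               histogram = buildHistogram(rnorm(1000, -100, 15)),
               provenance = "synthetic")
  empty <- generatePriorMask(binaryMask(matrix(0, 5, 5)), prior, seed = 1)
  expect_true(all(pixelValues(empty) == 0))

  full <- binaryMask(matrix(1, 100, 100))
  g <- generatePriorMask(full, prior, seed = 2)
  expect_identical(pixelValues(generatePriorMask(full, prior, seed = 2)),
                   pixelValues(g))
  v <- maskedValues(g)
  expect_lt(abs(mean(v) - (-100)), 3 * 15 / 100)  # CLT bound at 1e4 voxels

  # binned shape matches the Normal(adiposeMean, adiposeStd) density
  h <- buildHistogram(v, nBins = 64)
  mids <- (binEdges(h)[-1] + binEdges(h)[-65]) / 2
  ref <- new("DensityHistogram", binEdges = binEdges(h),
             counts = dnorm(mids, -100, 15))
  expect_gt(normalizedCorrelation(h, ref), 0.95)
})

test_that("externally supplied synthetic masks are adapted and clipped", {
  msk <- binaryMask(matrix(c(1, 0, 0, 1), 2, 2))
  g <- externalPriorMask(matrix(-80, 2, 2), msk)
  expect_equal(pixelValues(g), matrix(c(-80, 0, 0, -80), 2, 2))
  expect_error(externalPriorMask(matrix(0, 3, 3), msk), "shape")
})

test_that("prior models survive a JSON round trip", {
  prior <- suitePrior()
  f <- withr::local_tempfile(fileext = ".json")
  writePriorModel(prior, f)
  back <- readPriorModel(f)
  expect_equal(back@adiposeMean, prior@adiposeMean)
  expect_equal(back@adiposeStd, prior@adiposeStd)
  expect_equal(binCounts(back@histogram), binCounts(prior@histogram))
  expect_equal(binEdges(back@histogram), binEdges(prior@histogram))
})
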