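test_that("reference annotation applies the inclusive HU window inside the mask", {
  img <- densityImage(matrix(c(0, -100, 0, -50, 50, -50.5, 50.5, 25, 0),
                             3, 3))
  msk <- binaryMask(matrix(c(1, 1, 0, 1, 1, 1, 1, 1, 1), 3, 3))
  ref <- referenceAnnotation(img, msk)
  # 0 HU inside -> labeled; -100 HU inside -> not; 0 HU outside -> not;
  # bounds are inclusive, just-outside values excluded
  expect_equal(pixelValues(ref),
               matrix(c(1, 0, 0, 1, 1, 0, 0, 1, 1), 3, 3))
})

test_that("metrics honor their closed forms and units", {
  m <- binaryMask(matrix(c(1, 1, 0, 0), 2, 2))
  idm <- computeMetrics(m, m, spacing = c(1, 1), thickness = 1)
  expect_equal(idm@iou, 100); expect_equal(idm@dsc, 100)
  expect_equal(idm@avd, 0);  expect_equal(idm@rvd, 0)

  # disjoint equal-volume masks: zero overlap but zero volume difference
  a <- binaryMask(matrix(c(1, 0, 0, 0), 2, 2))
  b <- binaryMask(matrix(c(0, 1, 0, 0), 2, 2))
  dj <- computeMetrics(a, b, spacing = c(1, 1), thickness = 1)
  expect_equal(dj@iou, 0); expect_equal(dj@dsc, 0); expect_equal(dj@avd, 0)

  # 1000 surplus voxels of 1 mm^3 -> AVD exactly 0.001 L
  big <- matrix(0, 40, 40); big[1:25, 1:25] <- 1        # 625 -> need 1000
  pred <- binaryMask({ x <- matrix(0, 40, 40); x[1:40, 1:25] <- 1; x })
  ref <- binaryMask(matrix(0, 40, 40))
  av <- suppressWarnings(computeMetrics(pred, ref, spacing = c(1, 1),
                                        thickness = 1))
  expect_equal(av@avd, 1000 * 1e-6)
  expect_true(is.na(av@rvd))
})

test_that("DSC and IoU satisfy their algebraic relationship", {
  set.seed(55)
  for (i in 1:20) {
    a <- binaryMask(matrix(rbinom(100, 1, 0.4), 10, 10))
    b <- binaryMask(matrix(rbinom(100, 1, 0.4), 10, 10))
    m <- computeMetrics(a, b)
    iou <- m@iou / 100; dsc <- m@dsc / 100
    expect_equal(dsc, 2 * iou / (1 + iou), tolerance = 1e-12)
    expect_gte(m@dsc, m@iou)
    sym <- computeMetrics(b, a)
    expect_equal(sym@iou, m@iou); expect_equal(sym@dsc, m@dsc)
    expect_equal(sym@avd, m@avd)
  }
})

test_that("metrics are invariant to consistent slice reordering", {
  set.seed(66)
  p <- lapply(1:4, function(i) binaryMask(matrix(rbinom(64, 1, 0.3), 8, 8)))
  r <- lapply(1:4, function(i) binaryMask(matrix(rbinom(64, 1, 0.3), 8, 8)))
  m1 <- computeMetrics(p, r)
  perm <- c(3, 1, 4, 2)
  m2 <- computeMetrics(p[perm], r[perm])
  expect_equal(m1@iou, m2@iou); expect_equal(m1@dsc, m2@dsc)
  expect_equal(m1@avd, m2@avd); expect_equal(m1@rvd, m2@rvd)
})

test_that("compareAnnotations is computeMetrics with a as prediction", {
  set.seed(67)
  a <- binaryMask(matrix(rbinom(64, 1, 0.3), 8, 8))
  b <- binaryMask(matrix(rbinom(64, 1, 0.3), 8, 8))
  ca <- compareAnnotations(a, b)
  cm <- computeMetrics(a, b)
  expect_equal(ca@dsc, cm@dsc); expect_equal(ca@rvd, cm@rvd)
  expect_equal(compareAnnotations(a, a)@dsc, 100)
  expect_equal(compareAnnotations(a, b)@iou, compareAnnotations(b, a)@iou)
})

test_that("scan segmentation composes per-slice results without state leakage", {
  spec <- smallSpec()
  prior <- fitPrior(generateTrainingPairs(spec, n = 3, seed = 13))
  sams <- lapply(1:5, function(i) generatePhantom(spec, seed = 500 + i))
  imgs <- lapply(seq_along(sams), function(i) {
    im <- sams[[i]]@image; im@sliceIndex <- i; im })
  stack <- sliceStack(imgs)
  masks <- lapply(sams, function(s) s@adiposeMask)
  truth <- lapply(sams, function(s) s@edemaMask)

  cv <- segmentScan(stack, masks, prior, levelSetParams(), method = "cv_prior")
  expect_length(slices(cv), 5)
  for (i in 1:5)
    expect_gt(dscOf(slices(cv)[[i]], truth[[i]]), 85)

  # single-slice stack equals the single-slice run
  one <- segmentScan(sliceStack(imgs[1]), masks[1], prior, levelSetParams())
  direct <- runSegmentation(imgs[[1]], masks[[1]], prior, levelSetParams())
  expect_identical(pixelValues(slices(one)[[1]]), pixelValues(direct$mask))

  # method purity: interleaved calls reproduce the originals
  gm1 <- segmentScan(stack, masks, prior, method = "gmm")
  cv2 <- segmentScan(stack, masks, prior, levelSetParams(), method = "cv_prior")
  gm2 <- segmentScan(stack, masks, prior, method = "gmm")
  for (i in 1:5) {
    expect_identical(pixelValues(slices(cv2)[[i]]), pixelValues(slices(cv)[[i]]))
    expect_identical(pixelValues(slices(gm2)[[i]]), pixelValues(slices(gm1)[[i]]))
  }

  expect_error(segmentScan(stack, masks[1:3], prior), "misaligned")
})
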