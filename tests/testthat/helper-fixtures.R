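# Shared fixtures: all built in code, seeded.

# small, fast phantom for unit tests
smallSpec <- function(...) {
  args <- list(gridSize = 96L, ringInner = 26, ringOuter = 40,
               edemaBlobCount = 2L, blobRadiusRange = c(3, 6))
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(phantomSpec, args)
}

# noise-free configuration with effectively disjoint density supports:
# adipose N(-100, 5) never reaches -50 at these sample sizes, edema draws
# are truncated to [-50, 50]
disjointSpec <- function(...) {
  args <- list(adiposeStd = 5, noiseStd = 0)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(phantomSpec, args)
}

# the seeded default-phantom suite used by the benchmark-style tests
suiteSeeds <- 1000L + 1:20
suitePrior <- function() {
  fitPrior(generateTrainingPairs(phantomSpec(), n = 5, seed = 101))
}

# inject k small isolated edema blobs (disjoint from existing edema) into a
# phantom sample; returns modified image + ground-truth edema mask
addSmallBlobs <- function(sm, k = 4, radius = 2, seed = 9) {
  withr::with_seed(seed, {
    iv <- pixelValues(sm@image)
    em <- pixelValues(sm@edemaMask)
    ring <- pixelValues(sm@adiposeMask) == 1
    rows <- nrow(iv)
    ctr <- (rows + 1) / 2
    rr <- matrix(seq_len(rows), rows, rows)
    cc <- t(rr)
    placed <- 0
    guard <- 0
    while (placed < k && guard < 500) {
      guard <- guard + 1
      rad <- runif(1, sm@spec@ringInner + radius + 1,
                   sm@spec@ringOuter - radius - 1)
      ang <- runif(1, 0, 2 * pi)
      bcr <- ctr + rad * sin(ang); bcc <- ctr + rad * cos(ang)
      d <- ((rr - bcr)^2 + (cc - bcc)^2 <= radius^2) & ring
      if (sum(d) < 3 || any(em[d] == 1)) next
      u <- runif(sum(d), pnorm(-50, 0, 15), pnorm(50, 0, 15))
      iv[d] <- qnorm(u, 0, 15)
      em[d] <- 1
      placed <- placed + 1
    }
    stopifnot(placed == k)
    list(image = densityImage(iv, pixelSpacing = sm@spec@pixelSpacing,
                              sliceThickness = sm@spec@sliceThickness),
         edema = binaryMask(em))
  })
}

# number of ground-truth connected components touched by a prediction
countRecovered <- function(pred, truth) {
  lab <- EBImage::bwlabel(pixelValues(truth))
  n <- max(lab)
  if (n == 0) return(0L)
  sum(vapply(seq_len(n),
             function(l) any(pixelValues(pred)[lab == l] == 1), logical(1)))
}

dscOf <- function(pred, ref) computeMetrics(pred, ref)@dsc
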