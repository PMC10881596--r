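#' Specify a synthetic abdominal-CT-like phantom
#'
#' The phantom emulates the density structure the segmentation method
#' assumes: an annular subcutaneous adipose compartment of near-Gaussian
#' density (fat, strongly negative HU) embedded in a soft-tissue background,
#' with heterogeneous edema blobs overwriting part of the ring at near-water
#' densities truncated to the [-50, 50] HU edema window, plus additive
#' global acquisition noise. Ground-truth adipose and edema masks are exact
#' by construction.
#'
#' Defaults: 256x256 grid, ring radii 80/110 px, adipose -100 +/- 15 HU,
#' edema 0 +/- 15 HU, 4 blobs of 6-14 px radius, 5 HU noise, 30 HU
#' background, 1x1 mm pixels, 5 mm slices. These are fixture parameters
#' chosen so that fat and fluid densities are separated the way the
#' two-class mixture assumes; they are not measurements of real tissue.
#'
#' @param gridSize integer(2) or scalar, grid dimensions.
#' @param ringInner,ringOuter annulus radii in pixels (0 < inner < outer <
#'   min(gridSize)/2).
#' @param adiposeMean,adiposeStd adipose density model, HU.
#' @param edemaMean,edemaStd edema density model, HU; draws truncated to
#'   [-50, 50]; `edemaMean` must lie in that window.
#' @param edemaBlobCount number of edema blobs (>= 0).
#' @param blobRadiusRange numeric(2), blob disc radius range in pixels.
#' @param noiseStd additive global Gaussian noise, HU.
#' @param backgroundHU density outside the ring, HU.
#' @param pixelSpacing numeric(2), mm.
#' @param sliceThickness numeric(1), mm.
#' @return a [PhantomSpec-class].
#' @seealso [generatePhantom()], [generateTrainingPairs()]
#' @export
phantomSpec <- function(gridSize = c(256L, 256L), ringInner = 80,
                        ringOuter = 110, adiposeMean = -100, adiposeStd = 15,
                        edemaMean = 0, edemaStd = 15, edemaBlobCount = 4L,
                        blobRadiusRange = c(6, 14), noiseStd = 5,
                        backgroundHU = 30, pixelSpacing = c(1, 1),
                        sliceThickness = 5) {
  if (length(gridSize) == 1L) gridSize <- rep(gridSize, 2L)
  new("PhantomSpec", gridSize = as.integer(gridSize),
      ringInner = ringInner, ringOuter = ringOuter,
      adiposeMean = adiposeMean, adiposeStd = adiposeStd,
      edemaMean = edemaMean, edemaStd = edemaStd,
      edemaBlobCount = as.integer(edemaBlobCount),
      blobRadiusRange = as.numeric(blobRadiusRange),
      noiseStd = noiseStd, backgroundHU = backgroundHU,
      pixelSpacing = as.numeric(pixelSpacing),
      sliceThickness = sliceThickness)
}

# One global seed feeds a named sub-stream per sample index, so a suite can
# grow without perturbing earlier samples. Kept below 2^31 - 1.
sampleSeed <- function(seed, index) {
  as.integer((as.numeric(seed) + 999983 * as.numeric(index)) %% 2147483647)
}

truncNorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

discMask <- function(rows, cols, cr, cc, radius) {
  rr <- matrix(seq_len(rows), rows, cols)
  cc2 <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  (rr - cr)^2 + (cc2 - cc)^2 <= radius^2
}

#' Generate a synthetic phantom slice with exact ground truth
#'
#' Construction (all randomness from `seed`): the adipose ring is filled
#' with Normal(adiposeMean, adiposeStd) draws; each edema blob is a union
#' of 3-6 jittered overlapping discs (mimicking heterogeneous, discontinuous
#' edema shape) placed by rejection sampling inside the ring and clipped to
#' it; blob voxels are overwritten with Normal(edemaMean, edemaStd) draws
#' truncated to [-50, 50] HU; finally global Normal(0, noiseStd) noise is
#' added. The returned adipose mask is the full ring (edema included), the
#' edema mask is exact ground truth.
#'
#' @param spec a [PhantomSpec-class].
#' @param seed integer; the same (spec, seed) reproduces the sample bit for
#'   bit.
#' @return a [PhantomSample-class].
#' @examples
#' s <- generatePhantom(phantomSpec(gridSize = 64L, ringInner = 18,
#'                                  ringOuter = 28, edemaBlobCount = 1L,
#'                                  blobRadiusRange = c(3, 5)), seed = 7)
#' sum(pixelValues(s@edemaMask))
#' @export
generatePhantom <- function(spec, seed = 1L) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  withr::with_seed(as.integer(seed) %% 2147483647L, {
    rows <- spec@gridSize[1]; cols <- spec@gridSize[2]
    cr <- (rows + 1) / 2; cc <- (cols + 1) / 2
    rr <- matrix(seq_len(rows), rows, cols)
    cc2 <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
    dist <- sqrt((rr - cr)^2 + (cc2 - cc)^2)
    ring <- dist >= spec@ringInner & dist <= spec@ringOuter

    img <- matrix(spec@backgroundHU, rows, cols)
    img[ring] <- stats::rnorm(sum(ring), spec@adiposeMean, spec@adiposeStd)

    edema <- matrix(FALSE, rows, cols)
    if (spec@edemaBlobCount > 0L) {
      for (b in seq_len(spec@edemaBlobCount)) {
        r <- stats::runif(1, spec@blobRadiusRange[1], spec@blobRadiusRange[2])
        placed <- FALSE
        for (attempt in 1:100) {
          radLo <- spec@ringInner + r; radHi <- spec@ringOuter - r
          if (radLo >= radHi) break
          rad <- stats::runif(1, radLo, radHi)
          ang <- stats::runif(1, 0, 2 * pi)
          bcr <- cr + rad * sin(ang); bcc <- cc + rad * cos(ang)
          nDiscs <- sample(3:6, 1)
          blob <- matrix(FALSE, rows, cols)
          for (d in seq_len(nDiscs)) {
            jr <- if (d == 1) 0 else stats::rnorm(1, 0, r / 2)
            jc <- if (d == 1) 0 else stats::rnorm(1, 0, r / 2)
            dr <- r * stats::runif(1, 0.5, 1)
            blob <- blob | discMask(rows, cols, bcr + jr, bcc + jc, dr)
          }
          blob <- blob & ring
          if (sum(blob) >= 3L) { edema <- edema | blob; placed <- TRUE; break }
        }
        if (!placed)
          stop("edema blob of radius ", signif(r, 3),
               " cannot fit inside the adipose ring")
      }
      nEd <- sum(edema)
      if (nEd > 0L)
        img[edema] <- truncNorm(nEd, spec@edemaMean, spec@edemaStd, -50, 50)
    }
    if (spec@noiseStd > 0)
      img <- img + stats::rnorm(rows * cols, 0, spec@noiseStd)

    new("PhantomSample",
        image = densityImage(img, pixelSpacing = spec@pixelSpacing,
                             sliceThickness = spec@sliceThickness),
        adiposeMask = binaryMask(ring),
        edemaMask = binaryMask(edema),
        spec = spec, seed = as.integer(seed))
  })
}

#' Generate paired edema-free training masks
#'
#' Emulates, at desk scale, a training pool of paired 2D binary and
#' grayscale adipose masks from subjects without edema: each pair is an
#' edema-free phantom (`edemaBlobCount` forced to 0) restricted to its
#' adipose ring. The pairs feed [fitPrior()].
#'
#' @param spec a [PhantomSpec-class]; its blob count is ignored (set to 0).
#' @param n number of pairs (>= 1).
#' @param seed integer; pair i uses the i-th sub-stream of `seed`.
#' @return list of `n` two-element lists `(BinaryMask, GrayscaleMask)`.
#' @export
generateTrainingPairs <- function(spec, n, seed = 1L) {
  stopifnot(is(spec, "PhantomSpec"))
  if (n < 1L) stop("need n >= 1 training pairs")
  spec@edemaBlobCount <- 0L
  lapply(seq_len(n), function(i) {
    s <- generatePhantom(spec, seed = sampleSeed(seed, i))
    list(s@adiposeMask, applyMask(s@image, s@adiposeMask))
  })
}

setMethod("show", "PhantomSample", function(object) {
  cat(sprintf(
    "PhantomSample (seed %d) | %dx%d | adipose %d vox | edema %d vox\n",
    object@seed, nrow(object@image@values), ncol(object@image@values),
    sum(object@adiposeMask@values), sum(object@edemaMask@values)))
})
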