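#' @import methods
NULL

## ---- imaging core ----------------------------------------------------------

#' DensityImage: a 2D CT slice in Hounsfield units
#'
#' A single axial CT slice stored as a numeric matrix of densities in
#' Hounsfield units (HU), together with its physical pixel spacing and slice
#' thickness in millimetres and its ordinal position within a scan. The matrix
#' is the image domain over which all segmentation operates; indices are
#' row-major and 0-free (standard R 1-based indexing).
#'
#' @slot values numeric matrix of HU densities; must be finite and non-empty.
#' @slot pixelSpacing numeric(2), (row, col) spacing in mm; strictly positive.
#' @slot sliceThickness numeric(1), slice thickness in mm; strictly positive.
#' @slot sliceIndex integer(1), ordinal slice position within the scan.
#'
#' @seealso [densityImage()], [applyMask()], [readDensityImage()]
#' @export
setClass("DensityImage",
  representation(
    values = "matrix",
    pixelSpacing = "numeric",
    sliceThickness = "numeric",
    sliceIndex = "integer"
  )
)

setValidity("DensityImage", function(object) {
  msg <- character()
  v <- object@values
  if (length(v) == 0L) msg <- c(msg, "'values' must be a non-empty matrix")
  if (!is.numeric(v)) msg <- c(msg, "'values' must be numeric")
  if (length(v) && !all(is.finite(v))) msg <- c(msg, "'values' must be finite")
  if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
    msg <- c(msg, "'pixelSpacing' must be two strictly positive numbers (mm)")
  if (length(object@sliceThickness) != 1L || object@sliceThickness <= 0)
    msg <- c(msg, "'sliceThickness' must be a single strictly positive number (mm)")
  if (length(object@sliceIndex) != 1L)
    msg <- c(msg, "'sliceIndex' must be a single integer")
  if (length(msg)) msg else TRUE
})

#' BinaryMask: a binary segmentation mask
#'
#' A matrix of 0/1 values marking a tissue compartment (here the subcutaneous
#' adipose compartment, or an edema region). Background is zero. A mask is
#' always paired with a [DensityImage-class] of identical shape.
#'
#' @slot values numeric matrix with entries in \{0, 1\}.
#' @seealso [binaryMask()], [applyMask()], [writeMask()]
#' @export
setClass("BinaryMask", representation(values = "matrix"))

setValidity("BinaryMask", function(object) {
  v <- object@values
  if (length(v) == 0L) return("'values' must be a non-empty matrix")
  if (!is.numeric(v)) return("'values' must be numeric")
  if (!all(v %in% c(0, 1))) return("mask values must all be 0 or 1")
  TRUE
})

#' GrayscaleMask: an image restricted to a mask's support
#'
#' The product of a CT slice and a binary mask: density values inside the
#' mask support, exactly zero outside it. Because edema densities straddle
#' 0 HU, a genuine 0 HU voxel inside the support is indistinguishable from
#' background by value alone; every statistic computed from a GrayscaleMask
#' therefore consults the stored support mask, never a zero test.
#'
#' @slot values numeric matrix of HU, zero wherever support is 0.
#' @slot support a [BinaryMask-class] of the same shape.
#' @seealso [applyMask()], [maskedValues()]
#' @export
setClass("GrayscaleMask",
  representation(values = "matrix", support = "BinaryMask")
)

setValidity("GrayscaleMask", function(object) {
  s <- object@support@values
  v <- object@values
  if (!identical(dim(v), dim(s)))
    return("'values' and 'support' must have identical dimensions")
  if (any(v[s == 0] != 0))
    return("'values' must be exactly zero outside the support")
  TRUE
})

#' SliceStack: an ordered stack of slices or masks
#'
#' An ordered collection of [DensityImage-class] objects (or parallel
#' [BinaryMask-class] objects) from one scan, sharing shape and spacing, with
#' strictly increasing slice indices. Combining per-slice segmentations over
#' a stack yields the scan-level edema segmentation and volume.
#'
#' @slot slices list of DensityImage or BinaryMask objects.
#' @slot metadata list of scan-level metadata.
#' @seealso [sliceStack()], [segmentScan()], [computeMetrics()]
#' @export
setClass("SliceStack", representation(slices = "list", metadata = "list"))

setValidity("SliceStack", function(object) {
  sl <- object@slices
  if (length(sl) == 0L) return("a SliceStack needs at least one slice")
  ok <- vapply(sl, function(x) is(x, "DensityImage") || is(x, "BinaryMask"),
               logical(1))
  if (!all(ok)) return("slices must all be DensityImage or BinaryMask objects")
  dims <- vapply(sl, function(x) dim(x@values), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("all slices must share the same grid dimensions")
  if (all(vapply(sl, is, logical(1), "DensityImage"))) {
    sp <- vapply(sl, function(x) x@pixelSpacing, numeric(2))
    if (any(abs(sp - sp[, 1]) > 1e-9))
      return("all slices must share the same pixel spacing")
    idx <- vapply(sl, function(x) x@sliceIndex, integer(1))
    if (any(diff(idx) <= 0L))
      return("slice indices must be strictly increasing")
  }
  TRUE
})

## ---- histogram prior -------------------------------------------------------

#' DensityHistogram: a binned HU density distribution
#'
#' A histogram G over a fixed HU range with half-open bins
#' \eqn{[e_i, e_{i+1})} (last bin closed). Values outside the range are
#' clipped into the end bins, so the counts always sum to the number of
#' input values. Histogram pairs are compared by normalized correlation
#' ([normalizedCorrelation()]), which requires identical bin edges.
#'
#' @slot binEdges numeric(N+1), strictly increasing bin edges in HU.
#' @slot counts numeric(N), non-negative bin counts.
#' @seealso [buildHistogram()], [normalizedCorrelation()]
#' @export
setClass("DensityHistogram",
  representation(binEdges = "numeric", counts = "numeric")
)

setValidity("DensityHistogram", function(object) {
  e <- object@binEdges; ct <- object@counts
  if (length(e) < 3L) return("at least 2 bins are required")
  if (any(diff(e) <= 0)) return("'binEdges' must be strictly increasing")
  if (length(ct) != length(e) - 1L)
    return("'counts' must have length(binEdges) - 1 entries")
  if (any(!is.finite(ct)) || any(ct < 0))
    return("'counts' must be finite and non-negative")
  TRUE
})

#' PriorModel: an edema-free adipose density prior
#'
#' Summary of the density distribution of edema-free subcutaneous adipose
#' tissue: sample mean and standard deviation in HU plus the pooled fitted
#' histogram. Used both to generate synthetic edema-free grayscale masks
#' ([generatePriorMask()], the statistical stand-in for a mask-to-texture
#' generator network) and as the reference histogram for the level-set
#' prior constraint.
#'
#' @slot adiposeMean numeric(1), mean adipose density in HU.
#' @slot adiposeStd numeric(1), standard deviation in HU; strictly positive.
#' @slot histogram the pooled [DensityHistogram-class] of the training pool.
#' @slot provenance character description of the training data.
#' @seealso [fitPrior()], [generatePriorMask()], [writePriorModel()]
#' @export
setClass("PriorModel",
  representation(
    adiposeMean = "numeric",
    adiposeStd = "numeric",
    histogram = "DensityHistogram",
    provenance = "character"
  )
)

setValidity("PriorModel", function(object) {
  if (length(object@adiposeMean) != 1L || !is.finite(object@adiposeMean))
    return("'adiposeMean' must be a single finite number")
  if (length(object@adiposeStd) != 1L || !is.finite(object@adiposeStd) ||
      object@adiposeStd <= 0)
    return("'adiposeStd' must be a single strictly positive number")
  TRUE
})

## ---- GMM baseline ----------------------------------------------------------

#' TwoClassGMM: a two-component 1-D Gaussian mixture over HU densities
#'
#' The baseline density model: subcutaneous adipose tissue (low HU) and
#' edema fluid (near-water HU) as two Gaussian components fitted by EM.
#' Components are ordered so that the second (higher-mean) component is the
#' edema class.
#'
#' @slot weights numeric(2) mixing weights, in (0,1), summing to 1.
#' @slot means numeric(2) component means in HU, means[2] > means[1].
#' @slot stds numeric(2) component standard deviations in HU.
#' @slot logLik numeric(1), final log-likelihood.
#' @slot nIter integer(1), EM iterations used.
#' @slot llTrace numeric, per-iteration log-likelihood (non-decreasing).
#' @seealso [fitGMM()], [classifyEdemaGMM()]
#' @export
setClass("TwoClassGMM",
  representation(
    weights = "numeric", means = "numeric", stds = "numeric",
    logLik = "numeric", nIter = "integer", llTrace = "numeric"
  )
)

setValidity("TwoClassGMM", function(object) {
  w <- object@weights
  if (length(w) != 2L || abs(sum(w) - 1) > 1e-8 || any(w <= 0) || any(w >= 1))
    return("'weights' must be two values in (0,1) summing to 1")
  if (length(object@means) != 2L || any(!is.finite(object@means)))
    return("'means' must be two finite numbers")
  if (length(object@stds) != 2L || any(object@stds <= 0))
    return("'stds' must be two strictly positive numbers")
  TRUE
})

## ---- level set -------------------------------------------------------------

#' LevelSetParams: tunable parameters of the level-set segmentation
#'
#' All numerical and model parameters of the prior-constrained Chan-Vese
#' evolution. Constructed with [levelSetParams()], which supplies the
#' package defaults; see that help page for the meaning, units and default
#' of every field.
#'
#' @slot alpha numeric(1), weight of the adipose density prior term.
#' @slot beta numeric(1), weight of the contour-length (curvature) term, HU^2.
#' @slot epsilon numeric(1), Heaviside smoothing width in phi units (pixels).
#' @slot dt numeric(1), explicit time step.
#' @slot maxIter integer(1), iteration cap.
#' @slot reinitEvery integer(1), reinitialize phi to a signed distance
#'   function every this many iterations.
#' @slot convergeTol numeric(1), stop when the fraction of support voxels
#'   whose phi sign changed in an iteration falls below this.
#' @slot nBins integer(1), histogram bins for the prior term.
#' @slot histRange numeric(2), histogram HU range (lo, hi).
#' @slot priorMode character(1), "dissimilarity" or "literal_correlation".
#' @slot initMode character(1), "threshold", "gmm" or "checkerboard".
#' @seealso [levelSetParams()], [runSegmentation()]
#' @export
setClass("LevelSetParams",
  representation(
    alpha = "numeric", beta = "numeric", epsilon = "numeric", dt = "numeric",
    maxIter = "integer", reinitEvery = "integer", convergeTol = "numeric",
    nBins = "integer", histRange = "numeric",
    priorMode = "character", initMode = "character"
  )
)

setValidity("LevelSetParams", function(object) {
  msg <- character()
  if (object@alpha < 0 || object@beta < 0)
    msg <- c(msg, "'alpha' and 'beta' must be non-negative")
  if (object@dt <= 0) msg <- c(msg, "'dt' must be positive")
  if (object@epsilon <= 0) msg <- c(msg, "'epsilon' must be positive")
  if (object@maxIter < 1L) msg <- c(msg, "'maxIter' must be at least 1")
  if (object@reinitEvery < 1L) msg <- c(msg, "'reinitEvery' must be at least 1")
  if (!object@priorMode %in% c("dissimilarity", "literal_correlation"))
    msg <- c(msg, "'priorMode' must be 'dissimilarity' or 'literal_correlation'")
  if (!object@initMode %in% c("threshold", "gmm", "checkerboard"))
    msg <- c(msg, "'initMode' must be 'threshold', 'gmm' or 'checkerboard'")
  if (length(object@histRange) != 2L || diff(object@histRange) <= 0)
    msg <- c(msg, "'histRange' must be an increasing (lo, hi) pair")
  if (length(msg)) msg else TRUE
})

#' LevelSetState: the evolving level-set segmentation state
#'
#' The signed distance function phi over the image grid (phi >= 0 marks the
#' edema/inside region, phi < 0 the adipose/outside region), the current
#' region means C1 (edema) and C2 (adipose) in HU, the current value of the
#' histogram prior term F, the iteration counter and the current energy.
#'
#' @slot phi numeric matrix, signed distance function.
#' @slot C1 numeric(1), mean HU of the inside (edema) region.
#' @slot C2 numeric(1), mean HU of the outside (adipose) region.
#' @slot F numeric(1), current prior term value.
#' @slot iteration integer(1).
#' @slot energy numeric(1), current value of the segmentation energy.
#' @seealso [initPhi()], [evolveStep()], [runSegmentation()]
#' @export
setClass("LevelSetState",
  representation(
    phi = "matrix", C1 = "numeric", C2 = "numeric", F = "numeric",
    iteration = "integer", energy = "numeric"
  )
)

## ---- phantoms --------------------------------------------------------------

#' PhantomSpec: parameters of the synthetic CT phantom generator
#'
#' Describes a synthetic abdominal-CT-like slice: an annular subcutaneous
#' adipose compartment of near-Gaussian density with embedded heterogeneous
#' edema blobs whose densities lie in the [-50, 50] HU window, plus additive
#' acquisition noise. Constructed with [phantomSpec()], which documents the
#' defaults.
#'
#' @slot gridSize integer(2), (rows, cols).
#' @slot ringInner,ringOuter numeric(1), annulus radii in pixels.
#' @slot adiposeMean,adiposeStd numeric(1), adipose density model, HU.
#' @slot edemaMean,edemaStd numeric(1), edema density model, HU; draws are
#'   truncated to [-50, 50] HU.
#' @slot edemaBlobCount integer(1), number of edema blobs (>= 0).
#' @slot blobRadiusRange numeric(2), blob disc radius range in pixels.
#' @slot noiseStd numeric(1), additive global Gaussian noise, HU.
#' @slot backgroundHU numeric(1), density outside the adipose ring, HU.
#' @slot pixelSpacing numeric(2), mm. @slot sliceThickness numeric(1), mm.
#' @seealso [phantomSpec()], [generatePhantom()]
#' @export
setClass("PhantomSpec",
  representation(
    gridSize = "integer", ringInner = "numeric", ringOuter = "numeric",
    adiposeMean = "numeric", adiposeStd = "numeric",
    edemaMean = "numeric", edemaStd = "numeric",
    edemaBlobCount = "integer", blobRadiusRange = "numeric",
    noiseStd = "numeric", backgroundHU = "numeric",
    pixelSpacing = "numeric", sliceThickness = "numeric"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  g <- object@gridSize
  if (length(g) != 2L || any(g < 8L)) msg <- c(msg, "'gridSize' too small")
  if (!(object@ringInner > 0 && object@ringInner < object@ringOuter &&
        object@ringOuter < min(g) / 2))
    msg <- c(msg, "need 0 < ringInner < ringOuter < min(gridSize)/2")
  if (object@adiposeStd < 0 || object@edemaStd < 0 || object@noiseStd < 0)
    msg <- c(msg, "standard deviations must be non-negative")
  if (object@edemaBlobCount < 0L)
    msg <- c(msg, "'edemaBlobCount' must be non-negative")
  if (length(object@blobRadiusRange) != 2L || any(object@blobRadiusRange <= 0) ||
      diff(object@blobRadiusRange) < 0)
    msg <- c(msg, "'blobRadiusRange' must be an increasing positive pair")
  if (object@edemaMean < -50 || object@edemaMean > 50)
    msg <- c(msg, "'edemaMean' must lie inside [-50, 50] HU")
  if (any(object@pixelSpacing <= 0) || object@sliceThickness <= 0)
    msg <- c(msg, "spacing and thickness must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' PhantomSample: a generated phantom with exact ground truth
#'
#' @slot image the generated [DensityImage-class].
#' @slot adiposeMask [BinaryMask-class] of the full adipose ring (edema
#'   voxels included, matching what an adipose segmentor would return).
#' @slot edemaMask [BinaryMask-class] ground-truth edema.
#' @slot spec the [PhantomSpec-class] used.
#' @slot seed integer(1); same (spec, seed) reproduces the sample exactly.
#' @seealso [generatePhantom()]
#' @export
setClass("PhantomSample",
  representation(
    image = "DensityImage", adiposeMask = "BinaryMask",
    edemaMask = "BinaryMask", spec = "PhantomSpec", seed = "integer"
  )
)

setValidity("PhantomSample", function(object) {
  e <- object@edemaMask@values; a <- object@adiposeMask@values
  if (!identical(dim(e), dim(a)) ||
      !identical(dim(e), dim(object@image@values)))
    return("image and masks must share dimensions")
  if (any(e == 1 & a == 0))
    return("edema mask must be contained in the adipose mask")
  TRUE
})

## ---- evaluation ------------------------------------------------------------

#' MetricsReport: segmentation accuracy metrics
#'
#' Scan-level agreement between a predicted and a reference edema mask stack:
#' intersection over union (IoU, %), Dice similarity coefficient (DSC, %),
#' absolute volume difference (AVD, litres) and relative volume difference
#' (RVD = AVD / reference volume, %). Volumes come from voxel geometry
#' (pixel area x slice thickness, mm^3, converted to litres).
#'
#' @slot iou,dsc numeric(1), percent.
#' @slot avd numeric(1), litres.
#' @slot rvd numeric(1), percent; NA when the reference stack is empty.
#' @slot perSlice data.frame of per-slice counts and metrics.
#' @slot voxelVolume numeric(1), voxel volume in mm^3.
#' @seealso [computeMetrics()], [compareAnnotations()]
#' @export
setClass("MetricsReport",
  representation(
    iou = "numeric", dsc = "numeric", avd = "numeric", rvd = "numeric",
    perSlice = "data.frame", voxelVolume = "numeric"
  )
)
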