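#' Accessors for edemaCV classes
#'
#' Small accessor generics used across the package instead of direct slot
#' access: `pixelValues` returns the underlying numeric matrix of an image
#' or mask, `pixelSpacing`/`sliceThickness`/`sliceIndex` the geometry of a
#' [DensityImage-class], `maskSupport` the [BinaryMask-class] support of a
#' [GrayscaleMask-class], `binEdges`/`binCounts` the contents of a
#' [DensityHistogram-class], and `slices` the slice list of a
#' [SliceStack-class].
#'
#' @param x an edemaCV object.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases pixelValues pixelSpacing sliceThickness sliceIndex maskSupport
#'   binEdges binCounts slices
#' @examples
#' img <- densityImage(matrix(-100, 4, 4))
#' pixelValues(img)[1, 1]
#' pixelSpacing(img)
NULL

#' @rdname accessors
#' @export
setGeneric("pixelValues", function(x) standardGeneric("pixelValues"))
#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))
#' @rdname accessors
#' @export
setGeneric("sliceThickness", function(x) standardGeneric("sliceThickness"))
#' @rdname accessors
#' @export
setGeneric("sliceIndex", function(x) standardGeneric("sliceIndex"))
#' @rdname accessors
#' @export
setGeneric("maskSupport", function(x) standardGeneric("maskSupport"))
#' @rdname accessors
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))
#' @rdname accessors
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))
#' @rdname accessors
#' @export
setGeneric("slices", function(x) standardGeneric("slices"))

#' @rdname accessors
#' @export
setMethod("pixelValues", "DensityImage", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("pixelValues", "BinaryMask", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("pixelValues", "GrayscaleMask", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("pixelSpacing", "DensityImage", function(x) x@pixelSpacing)
#' @rdname accessors
#' @export
setMethod("sliceThickness", "DensityImage", function(x) x@sliceThickness)
#' @rdname accessors
#' @export
setMethod("sliceIndex", "DensityImage", function(x) x@sliceIndex)
#' @rdname accessors
#' @export
setMethod("maskSupport", "GrayscaleMask", function(x) x@support)
#' @rdname accessors
#' @export
setMethod("binEdges", "DensityHistogram", function(x) x@binEdges)
#' @rdname accessors
#' @export
setMethod("binCounts", "DensityHistogram", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("slices", "SliceStack", function(x) x@slices)

#' @describeIn applyMask restrict a CT slice to a binary mask's support
#' @export
setGeneric("applyMask", function(image, mask) standardGeneric("applyMask"))
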