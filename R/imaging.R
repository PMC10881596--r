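#' Construct a DensityImage
#'
#' @param values numeric matrix of densities in HU.
#' @param pixelSpacing numeric(2) (row, col) pixel spacing in mm.
#' @param sliceThickness slice thickness in mm.
#' @param sliceIndex ordinal slice position in the scan.
#' @return a [DensityImage-class].
#' @examples
#' img <- densityImage(matrix(-100, 8, 8), pixelSpacing = c(1, 1))
#' @export
densityImage <- function(values, pixelSpacing = c(1, 1), sliceThickness = 5,
                         sliceIndex = 1L) {
  new("DensityImage", values = values,
      pixelSpacing = as.numeric(pixelSpacing),
      sliceThickness = as.numeric(sliceThickness),
      sliceIndex = as.integer(sliceIndex))
}

#' Construct a BinaryMask
#'
#' @param values numeric or logical matrix; logical is coerced to 0/1.
#' @return a [BinaryMask-class].
#' @examples
#' m <- binaryMask(matrix(c(1, 0, 0, 1), 2, 2))
#' @export
binaryMask <- function(values) {
  storage.mode(values) <- "double"
  new("BinaryMask", values = values)
}

#' Construct a SliceStack
#'
#' @param slices list of [DensityImage-class] or [BinaryMask-class] objects.
#' @param metadata optional list of scan-level metadata.
#' @return a [SliceStack-class].
#' @export
sliceStack <- function(slices, metadata = list()) {
  new("SliceStack", slices = slices, metadata = metadata)
}

#' Restrict an image to a mask: the grayscale adipose mask
#'
#' Multiplies a CT slice by a binary segmentation mask, giving a grayscale
#' tissue mask: the density values inside the compartment, zero outside.
#' Applied to an edema patient's slice and their adipose segmentation this
#' yields the (possibly edematous) grayscale adipose mask that the level-set
#' segmentation operates on.
#'
#' @param image a [DensityImage-class] (or plain numeric matrix).
#' @param mask a [BinaryMask-class] of the same shape.
#' @return a [GrayscaleMask-class]; values are the elementwise product,
#'   support is `mask`.
#' @examples
#' img <- densityImage(matrix(c(10, 30, 20, 40), 2, 2))
#' msk <- binaryMask(matrix(c(1, 0, 0, 1), 2, 2))
#' pixelValues(applyMask(img, msk))
#' @export
setMethod("applyMask", signature("DensityImage", "BinaryMask"),
  function(image, mask) {
    iv <- image@values; mv <- mask@values
    if (!identical(dim(iv), dim(mv)))
      stop("shape mismatch: image is ", paste(dim(iv), collapse = "x"),
           ", mask is ", paste(dim(mv), collapse = "x"))
    new("GrayscaleMask", values = iv * mv, support = mask)
  })

#' @describeIn applyMask matrix input is wrapped with unit spacing
#' @export
setMethod("applyMask", signature("matrix", "BinaryMask"),
  function(image, mask) applyMask(densityImage(image), mask))

#' Extract the in-support density values of a grayscale mask
#'
#' Returns the densities of the voxels inside the support mask, in
#' column-major order. This is the only sanctioned way to pool densities
#' from a [GrayscaleMask-class]: selecting by `value != 0` would silently
#' drop genuine 0 HU voxels, which sit in the middle of the edema density
#' window.
#'
#' @param gmask a [GrayscaleMask-class].
#' @return numeric vector of length `sum(mask)`.
#' @examples
#' g <- applyMask(matrix(0, 2, 2), binaryMask(matrix(c(1, 1, 0, 0), 2, 2)))
#' maskedValues(g)  # two genuine 0 HU voxels, not dropped
#' @export
maskedValues <- function(gmask) {
  stopifnot(is(gmask, "GrayscaleMask"))
  gmask@values[gmask@support@values == 1]
}

## ---- show methods ----------------------------------------------------------

setMethod("show", "DensityImage", function(object) {
  v <- object@values
  cat(sprintf(
    "DensityImage %dx%d | HU range [%.1f, %.1f] | spacing %.2fx%.2f mm | thickness %.1f mm | slice %d\n",
    nrow(v), ncol(v), min(v), max(v),
    object@pixelSpacing[1], object@pixelSpacing[2],
    object@sliceThickness, object@sliceIndex))
})

setMethod("show", "BinaryMask", function(object) {
  v <- object@values
  cat(sprintf("BinaryMask %dx%d | %d foreground voxels (%.1f%%)\n",
              nrow(v), ncol(v), sum(v), 100 * mean(v)))
})

setMethod("show", "GrayscaleMask", function(object) {
  v <- maskedValues(object)
  cat(sprintf("GrayscaleMask %dx%d | support %d voxels",
              nrow(object@values), ncol(object@values), length(v)))
  if (length(v))
    cat(sprintf(" | in-support HU range [%.1f, %.1f]", min(v), max(v)))
  cat("\n")
})

setMethod("show", "SliceStack", function(object) {
  cat(sprintf("SliceStack of %d %s slice(s)\n", length(object@slices),
              class(object@slices[[1]])))
})
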