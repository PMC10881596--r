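## File I/O: NIfTI via RNifti; 16-bit grayscale PNG + JSON sidecar as a
## dependency-light alternative. png::readPNG reads 16-bit PNGs but writePNG
## emits only 8 bits per sample, so the 16-bit writer is implemented here
## (zlib stream from memCompress, CRC32 below).

guessFormat <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.png$", path, ignore.case = TRUE)) return("png")
  stop("cannot infer format from extension of '", path, "'")
}

sidecarPath <- function(path) sub("\\.png$", ".json", path, ignore.case = TRUE)

#' Read a CT slice from NIfTI or 16-bit PNG
#'
#' NIfTI files carry HU values and spacing directly. 16-bit PNGs store
#' unsigned counts; they are de-offset to HU with the `intercept` recorded in
#' the JSON sidecar (`<name>.json` next to the image, fields `intercept`,
#' `spacing_mm`, `thickness_mm`, optional `slice_index`), i.e.
#' HU = stored + intercept.
#'
#' @param path file path (.nii/.nii.gz or .png).
#' @param format "auto" (by extension), "nifti" or "png16".
#' @return a [DensityImage-class].
#' @seealso [writeDensityImage()], [readMask()]
#' @export
readDensityImage <- function(path, format = c("auto", "nifti", "png16")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (guessFormat(path) == "nifti") "nifti" else "png16"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    pd <- RNifti::niftiHeader(img)$pixdim  # (qfac, d1, d2, d3, ...)
    d <- dim(img)
    if (length(d) > 2L) {
      if (any(d[-(1:2)] != 1L))
        stop("non-2D payload: '", path, "' has dimensions ",
             paste(d, collapse = "x"))
      img <- array(img, dim = d[1:2])
    }
    if (length(pd) < 3L || any(pd[2:3] <= 0))
      stop("missing or invalid pixel spacing metadata in '", path, "'")
    thick <- if (length(pd) >= 4L && pd[4] > 0) pd[4] else 1
    densityImage(matrix(as.numeric(img), nrow = d[1], ncol = d[2]),
                 pixelSpacing = pd[2:3], sliceThickness = thick)
  } else {
    raw01 <- png::readPNG(path)
    if (length(dim(raw01)) != 2L)
      stop("non-2D payload: expected a grayscale PNG at '", path, "'")
    sc <- sidecarPath(path)
    if (!file.exists(sc))
      stop("missing spacing metadata: sidecar '", sc, "' not found")
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    for (f in c("intercept", "spacing_mm", "thickness_mm"))
      if (is.null(meta[[f]])) stop("sidecar '", sc, "' lacks field '", f, "'")
    stored <- round(raw01 * 65535)
    densityImage(stored + meta$intercept,
                 pixelSpacing = as.numeric(meta$spacing_mm),
                 sliceThickness = meta$thickness_mm,
                 sliceIndex = if (is.null(meta$slice_index)) 1L
                              else as.integer(meta$slice_index))
  }
}

#' Write a CT slice to NIfTI or 16-bit PNG
#'
#' The PNG path writes a 16-bit grayscale image holding
#' `round(HU) - intercept` plus a JSON sidecar with the intercept and
#' geometry, so that [readDensityImage()] round-trips integer HU exactly.
#'
#' @param image a [DensityImage-class].
#' @param path output path (.nii/.nii.gz or .png).
#' @param format "auto", "nifti" or "png16".
#' @param intercept HU offset for the PNG encoding (stored = HU - intercept);
#'   stored values must land in [0, 65535].
#' @return `path`, invisibly.
#' @export
writeDensityImage <- function(image, path,
                              format = c("auto", "nifti", "png16"),
                              intercept = -1024) {
  stopifnot(is(image, "DensityImage"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (guessFormat(path) == "nifti") "nifti" else "png16"
  if (format == "nifti") {
    # oro.nifti keeps pixdim[4] (the slice thickness) for single-slice
    # files, which RNifti's writer zeroes out
    nii <- oro.nifti::nifti(array(image@values, c(dim(image@values), 1L)),
                            pixdim = c(1, image@pixelSpacing,
                                       image@sliceThickness),
                            datatype = 64, bitpix = 64L)
    stem <- sub("\\.nii(\\.gz)?$", "", path)
    oro.nifti::writeNIfTI(nii, stem,
                          gzipped = grepl("\\.gz$", path), verbose = FALSE)
  } else {
    stored <- round(image@values) - intercept
    if (any(stored < 0 | stored > 65535))
      stop("HU values do not fit a 16-bit PNG with intercept ", intercept)
    writePNG16(stored, path)
    jsonlite::write_json(
      list(intercept = intercept, spacing_mm = image@pixelSpacing,
           thickness_mm = image@sliceThickness,
           slice_index = image@sliceIndex),
      sidecarPath(path), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write / read a binary mask
#'
#' Masks round-trip bit-exactly through both formats. `writeMask` validates
#' the mask (values strictly in \{0,1\}) before touching the file system.
#'
#' @param mask a [BinaryMask-class].
#' @param path output path (.nii/.nii.gz or .png).
#' @param format "auto" (by extension), "nifti" or "png".
#' @return `writeMask`: `path` invisibly; `readMask`: a [BinaryMask-class].
#' @export
writeMask <- function(mask, path, format = c("auto", "nifti", "png")) {
  stopifnot(is(mask, "BinaryMask"))
  validObject(mask)
  format <- match.arg(format)
  if (format == "auto") format <- guessFormat(path)
  if (format == "nifti") {
    RNifti::writeNifti(RNifti::asNifti(mask@values), path)
  } else {
    png::writePNG(mask@values, path)
  }
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path, format = c("auto", "nifti", "png")) {
  format <- match.arg(format)
  if (format == "auto") format <- guessFormat(path)
  if (!file.exists(path)) stop("file not found: ", path)
  v <- if (format == "nifti") {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) > 2L) {
      if (any(d[-(1:2)] != 1L)) stop("non-2D mask in '", path, "'")
      d <- d[1:2]
    }
    matrix(as.numeric(img), d[1], d[2])
  } else {
    round(png::readPNG(path))
  }
  binaryMask(v)
}

## ---- minimal 16-bit grayscale PNG writer -----------------------------------

crc32Table <- local({
  poly <- -306674912L  # 0xEDB88320 as signed int32
  tab <- integer(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(poly, bitwShiftR(c, 1L))
           else bitwShiftR(c, 1L)
    }
    tab[i + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  c <- -1L  # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (x in b)
    c <- bitwXor(crc32Table[bitwAnd(bitwXor(c, x), 255L) + 1L],
                 bitwShiftR(c, 8L))
  bitwXor(c, -1L)
}

int32be <- function(x) {
  # x may exceed .Machine$integer.max semantics only for crc (already int)
  writeBin(as.integer(x), raw(), size = 4L, endian = "big")
}

pngChunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(int32be(length(data)), body, int32be(crc32(body)))
}

# 'stored' is a numeric matrix of integers in [0, 65535]; rows are scanlines.
writePNG16 <- function(stored, path) {
  h <- nrow(stored); w <- ncol(stored)
  ihdr <- c(int32be(w), int32be(h),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # bit depth 16, grayscale
  # scanlines: filter byte 0 + big-endian 16-bit samples, row by row
  m <- t(stored)  # column-major over t() walks pixels in scanline order
  hi <- as.raw(m %/% 256); lo <- as.raw(m %% 256)
  px <- as.raw(rbind(hi, lo))  # interleave high/low bytes per pixel
  dim(px) <- NULL
  rowsz <- 2L * w
  scan <- raw(h * (rowsz + 1L))
  for (r in seq_len(h)) {
    at <- (r - 1L) * (rowsz + 1L)
    scan[at + 1L] <- as.raw(0L)
    scan[at + 1L + seq_len(rowsz)] <- px[(r - 1L) * rowsz + seq_len(rowsz)]
  }
  idat <- memCompress(scan, type = "gzip")  # zlib-wrapped deflate
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           pngChunk("IHDR", ihdr),
           pngChunk("IDAT", idat),
           pngChunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}
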