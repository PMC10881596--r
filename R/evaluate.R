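#' Reproducible part of the reference-annotation protocol
#'
#' The reference edema annotation starts from a density threshold: every
#' voxel inside the subcutaneous adipose mask whose density lies in the
#' inclusive [-50, 50] HU window is labeled edema; tissue outside the
#' subcutaneous region is removed by the mask. The subsequent manual editing
#' stage of the protocol (deleting non-edema, adding missed edema) is a
#' human step and is deliberately not automated here.
#'
#' @param image a [DensityImage-class].
#' @param adiposeMask a [BinaryMask-class] of the same shape.
#' @param window inclusive HU window, default c(-50, 50).
#' @return a [BinaryMask-class].
#' @export
referenceAnnotation <- function(image, adiposeMask, window = c(-50, 50)) {
  stopifnot(is(image, "DensityImage"), is(adiposeMask, "BinaryMask"))
  iv <- image@values; mv <- adiposeMask@values
  if (!identical(dim(iv), dim(mv))) stop("shape mismatch")
  binaryMask((iv >= window[1] & iv <= window[2] & mv == 1) * 1)
}

asMaskList <- function(x) {
  if (is(x, "SliceStack")) return(x@slices)
  if (is(x, "BinaryMask")) return(list(x))
  stopifnot(is.list(x))
  x
}

#' Segment a whole scan, slice by slice
#'
#' Applies the chosen segmentation method independently to every slice of
#' the stack and combines the per-slice results into the scan-level edema
#' segmentation. "cv_prior" runs the prior-constrained level set
#' ([runSegmentation()]); "gmm" fits the two-class mixture to each slice's
#' masked densities and applies the MAP rule ([classifyEdemaGMM()]). A
#' slice whose segmentation fails (e.g. degenerate mixture fit, vanished
#' contour) yields an empty mask and is flagged in the output metadata
#' rather than aborting the scan.
#'
#' @param stack a [SliceStack-class] of [DensityImage-class] slices.
#' @param masks a parallel [SliceStack-class] (or list) of adipose
#'   [BinaryMask-class] objects.
#' @param prior a [PriorModel-class] (needed for "cv_prior" with alpha > 0).
#' @param params a [LevelSetParams-class].
#' @param method "cv_prior" or "gmm".
#' @return a [SliceStack-class] of edema [BinaryMask-class] objects, slice
#'   order preserved; `metadata$failed` is a logical vector flagging slices
#'   that returned empty after a failure.
#' @export
segmentScan <- function(stack, masks, prior = NULL,
                        params = levelSetParams(),
                        method = c("cv_prior", "gmm")) {
  method <- match.arg(method)
  imgs <- if (is(stack, "SliceStack")) stack@slices else stack
  mks <- asMaskList(masks)
  if (length(imgs) != length(mks))
    stop("misaligned stacks: ", length(imgs), " images vs ",
         length(mks), " masks")
  failed <- logical(length(imgs))
  out <- vector("list", length(imgs))
  for (i in seq_along(imgs)) {
    img <- imgs[[i]]; msk <- mks[[i]]
    if (!identical(dim(img@values), dim(msk@values)))
      stop("misaligned stacks: slice ", i, " shapes differ")
    res <- tryCatch({
      if (method == "gmm") {
        gmm <- fitGMM(maskedValues(applyMask(img, msk)))
        classifyEdemaGMM(img, msk, gmm)
      } else {
        r <- runSegmentation(img, msk, prior, params)
        if (r$vanished) failed[i] <- TRUE
        r$mask
      }
    }, error = function(e) {
      failed[i] <<- TRUE
      binaryMask(matrix(0, nrow(img@values), ncol(img@values)))
    })
    out[[i]] <- res
  }
  sliceStack(out, metadata = list(method = method, failed = failed))
}

#' Segmentation accuracy metrics
#'
#' Computes, over aligned prediction/reference mask stacks:
#' IoU = 100 |A∩B| / |A∪B|, DSC = 200 |A∩B| / (|A|+|B|),
#' AVD = |vol(A) − vol(B)| in litres (voxel volume = pixel area x slice
#' thickness, mm^3, x 1e-6), and RVD = 100 AVD / vol(B) with B the
#' reference. Voxel counts are pooled over all slices of the scan. When
#' both masks are entirely empty the overlap metrics are reported as 100
#' (perfect agreement); when only the reference is empty RVD is undefined
#' and reported as NA.
#'
#' @param pred,ref [SliceStack-class] (or list, or single
#'   [BinaryMask-class]) of prediction and reference masks.
#' @param spacing numeric(2) pixel spacing in mm.
#' @param thickness slice thickness in mm.
#' @return a [MetricsReport-class].
#' @examples
#' a <- binaryMask(matrix(c(1, 1, 0, 0), 2, 2))
#' b <- binaryMask(matrix(c(1, 0, 1, 0), 2, 2))
#' computeMetrics(a, b, spacing = c(1, 1), thickness = 1)
#' @export
computeMetrics <- function(pred, ref, spacing = c(1, 1), thickness = 5) {
  p <- asMaskList(pred); r <- asMaskList(ref)
  if (length(p) != length(r)) stop("misaligned stacks")
  voxVol <- prod(spacing) * thickness  # mm^3
  per <- lapply(seq_along(p), function(i) {
    pv <- p[[i]]@values; rv <- r[[i]]@values
    if (!identical(dim(pv), dim(rv))) stop("slice ", i, " shapes differ")
    data.frame(slice = i, n_pred = sum(pv), n_ref = sum(rv),
               n_inter = sum(pv * rv), n_union = sum(pmax(pv, rv)))
  })
  per <- do.call(rbind, per)
  per$iou <- ifelse(per$n_union > 0, 100 * per$n_inter / per$n_union, 100)
  per$dsc <- ifelse(per$n_pred + per$n_ref > 0,
                    200 * per$n_inter / (per$n_pred + per$n_ref), 100)
  nInter <- sum(per$n_inter); nUnion <- sum(per$n_union)
  nPred <- sum(per$n_pred); nRef <- sum(per$n_ref)
  iou <- if (nUnion > 0) 100 * nInter / nUnion else 100
  dsc <- if (nPred + nRef > 0) 200 * nInter / (nPred + nRef) else 100
  avd <- abs(nPred - nRef) * voxVol * 1e-6  # litres
  rvd <- if (nRef > 0) 100 * avd / (nRef * voxVol * 1e-6) else {
    warning("empty reference: RVD undefined, reported as NA")
    NA_real_
  }
  new("MetricsReport", iou = iou, dsc = dsc, avd = avd, rvd = rvd,
      perSlice = per, voxelVolume = voxVol)
}

#' Pairwise comparison of two annotation sets
#'
#' Evaluates one grader's annotation stack against another's with
#' [computeMetrics()], treating `a` as the prediction and `b` as the
#' reference. IoU, DSC and AVD are symmetric in the two arguments; RVD is
#' not (it is normalized by `b`), so the direction is recorded in the
#' per-slice table's attributes.
#'
#' @param a,b aligned annotation stacks ([SliceStack-class] or list of
#'   [BinaryMask-class]).
#' @inheritParams computeMetrics
#' @return a [MetricsReport-class].
#' @export
compareAnnotations <- function(a, b, spacing = c(1, 1), thickness = 5) {
  rep <- computeMetrics(a, b, spacing = spacing, thickness = thickness)
  attr(rep@perSlice, "rvd_reference") <- "b"
  rep
}

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(
    "MetricsReport | IoU %.1f%% | DSC %.1f%% | AVD %.4f L | RVD %s | %d slice(s)\n",
    object@iou, object@dsc, object@avd,
    if (is.na(object@rvd)) "NA" else sprintf("%.1f%%", object@rvd),
    nrow(object@perSlice)))
})
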