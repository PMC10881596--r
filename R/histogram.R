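#' Build a density histogram over a fixed HU range
#'
#' Bins are half-open \eqn{[e_i, e_{i+1})} with the last bin closed. Values
#' outside `range` are clipped into the end bins, so the counts always sum
#' to `length(values)`. Defaults (64 bins over [-200, 100] HU) cover the fat
#' and fluid densities this package deals in.
#'
#' @param values numeric vector of HU densities; must be non-empty.
#' @param nBins number of bins (>= 2).
#' @param range numeric(2) HU range (lo, hi).
#' @return a [DensityHistogram-class].
#' @examples
#' h <- buildHistogram(c(-100, -100, 0), nBins = 2, range = c(-200, 100))
#' binCounts(h)  # 2 1
#' @export
buildHistogram <- function(values, nBins = 64L, range = c(-200, 100)) {
  if (length(values) == 0L) stop("cannot build a histogram from no values")
  stopifnot(nBins >= 2L, length(range) == 2L, range[2] > range[1])
  x <- pmin(pmax(values, range[1]), range[2])
  edges <- seq(range[1], range[2], length.out = nBins + 1L)
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  new("DensityHistogram", binEdges = edges,
      counts = as.numeric(tabulate(idx, nbins = as.integer(nBins))))
}

histVariance <- function(h) {
  g <- h@counts
  sum((g - mean(g))^2)
}

#' Normalized correlation of two density histograms
#'
#' The mean-centred correlation
#' \deqn{F = \frac{\sum_i (G_1(i)-\bar G_1)(G_2(i)-\bar G_2)}
#'   {\sqrt{\sum_i (G_1(i)-\bar G_1)^2 \sum_i (G_2(i)-\bar G_2)^2}}}
#' with \eqn{\bar G = \sum_i G(i)/N} over the N shared bins. It is 1 when
#' the histogram shapes match up to positive affine scaling of the counts,
#' and lies in [-1, 1] always (Cauchy-Schwarz). Both histograms must use
#' identical bin edges and neither may be constant across bins (the
#' denominator would vanish).
#'
#' @param h1,h2 [DensityHistogram-class] objects with identical bin edges.
#' @return a scalar in [-1, 1].
#' @seealso [priorDissimilarity()]
#' @export
normalizedCorrelation <- function(h1, h2) {
  stopifnot(is(h1, "DensityHistogram"), is(h2, "DensityHistogram"))
  if (length(h1@binEdges) != length(h2@binEdges) ||
      any(h1@binEdges != h2@binEdges))
    stop("histograms must share identical bin edges")
  d1 <- h1@counts - mean(h1@counts)
  d2 <- h2@counts - mean(h2@counts)
  v1 <- sum(d1^2); v2 <- sum(d2^2)
  if (v1 == 0 || v2 == 0)
    stop("zero-variance histogram: correlation undefined for constant counts")
  sum(d1 * d2) / sqrt(v1 * v2)
}

#' Dissimilarity between a region histogram and the adipose prior
#'
#' `1 - normalizedCorrelation(hRegion, hPrior)`, in [0, 2]: exactly 0 when
#' the region's density histogram matches the edema-free adipose prior, and
#' growing as the region is contaminated by edema (whose near-water
#' densities add a second mode the unimodal prior lacks). This is the
#' default form of the level-set prior term: driving it down pushes the
#' adipose (outside) region towards edema-free composition.
#'
#' @inheritParams normalizedCorrelation
#' @param hRegion histogram of the candidate adipose region.
#' @param hPrior the prior histogram.
#' @return a scalar in [0, 2].
#' @export
priorDissimilarity <- function(hRegion, hPrior) {
  1 - normalizedCorrelation(hRegion, hPrior)
}

#' Fit the edema-free adipose density prior
#'
#' Pools the in-support densities of paired (binary, grayscale) adipose
#' masks from edema-free subjects and records their sample mean, standard
#' deviation and pooled histogram. The result drives the synthetic prior
#' mask generator and supplies the reference histogram for the level-set
#' constraint.
#'
#' @param pairs list of two-element lists `(BinaryMask, GrayscaleMask)`, as
#'   returned by [generateTrainingPairs()].
#' @param nBins,range histogram settings (see [buildHistogram()]).
#' @param provenance free-text description of the training pool.
#' @return a [PriorModel-class].
#' @export
fitPrior <- function(pairs, nBins = 64L, range = c(-200, 100),
                     provenance = "edema-free adipose training pairs") {
  if (length(pairs) == 0L) stop("need at least one training pair")
  pooled <- unlist(lapply(pairs, function(p) {
    g <- p[[2]]
    stopifnot(is(g, "GrayscaleMask"))
    maskedValues(g)
  }))
  if (length(pooled) == 0L) stop("training pairs have empty support")
  s <- stats::sd(pooled)
  if (!is.finite(s) || s == 0)
    stop("degenerate std: pooled adipose densities are constant")
  new("PriorModel",
      adiposeMean = mean(pooled), adiposeStd = s,
      histogram = buildHistogram(pooled, nBins = nBins, range = range),
      provenance = provenance)
}

#' Generate a synthetic edema-free grayscale mask from the prior
#'
#' Fills a binary adipose mask with i.i.d. draws from the fitted
#' Normal(adiposeMean, adiposeStd) density model, zero outside the support.
#' This is the statistical prior generator: it plays the role of a
#' mask-to-texture generator network, producing an edema-free grayscale
#' adipose mask for any input binary mask. An externally generated mask
#' (e.g. from a trained image-to-image network) can be slotted in instead
#' via [externalPriorMask()]; downstream code only sees a
#' [GrayscaleMask-class] either way.
#'
#' @param mask a [BinaryMask-class].
#' @param prior a [PriorModel-class].
#' @param seed integer seed; output is deterministic given (mask, prior, seed).
#' @return a [GrayscaleMask-class].
#' @export
generatePriorMask <- function(mask, prior, seed = 1L) {
  stopifnot(is(mask, "BinaryMask"), is(prior, "PriorModel"))
  v <- matrix(0, nrow(mask@values), ncol(mask@values))
  inside <- mask@values == 1
  n <- sum(inside)
  if (n > 0L)
    v[inside] <- withr::with_seed(as.integer(seed),
      stats::rnorm(n, prior@adiposeMean, prior@adiposeStd))
  new("GrayscaleMask", values = v, support = mask)
}

#' Adapt an externally generated synthetic mask
#'
#' Wraps a density matrix produced outside this package (for instance by a
#' trained mask-to-texture network) as the synthetic edema-free grayscale
#' mask, zeroing anything outside the binary support and validating shape.
#'
#' @param values numeric matrix of HU densities.
#' @param mask the [BinaryMask-class] the values were generated for.
#' @return a [GrayscaleMask-class].
#' @export
externalPriorMask <- function(values, mask) {
  stopifnot(is(mask, "BinaryMask"))
  if (!identical(dim(values), dim(mask@values)))
    stop("shape mismatch between external values and mask")
  new("GrayscaleMask", values = values * mask@values, support = mask)
}

#' Serialize / restore a PriorModel as JSON
#'
#' @param prior a [PriorModel-class].
#' @param path JSON file path.
#' @return `writePriorModel`: `path` invisibly; `readPriorModel`: a
#'   [PriorModel-class].
#' @export
writePriorModel <- function(prior, path) {
  stopifnot(is(prior, "PriorModel"))
  jsonlite::write_json(
    list(adipose_mean = prior@adiposeMean, adipose_std = prior@adiposeStd,
         bin_edges = prior@histogram@binEdges,
         counts = prior@histogram@counts,
         provenance = prior@provenance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePriorModel
#' @export
readPriorModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("PriorModel",
      adiposeMean = j$adipose_mean, adiposeStd = j$adipose_std,
      histogram = new("DensityHistogram",
                      binEdges = as.numeric(j$bin_edges),
                      counts = as.numeric(j$counts)),
      provenance = as.character(j$provenance))
}

setMethod("show", "DensityHistogram", function(object) {
  cat(sprintf("DensityHistogram | %d bins over [%g, %g] HU | %g values\n",
              length(object@counts), min(object@binEdges),
              max(object@binEdges), sum(object@counts)))
})

setMethod("show", "PriorModel", function(object) {
  cat(sprintf(
    "PriorModel | adipose %.1f +/- %.1f HU | %d-bin histogram | %s\n",
    object@adiposeMean, object@adiposeStd, length(object@histogram@counts),
    object@provenance))
})
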