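#' Construct level-set segmentation parameters
#'
#' Defaults, with units:
#' \describe{
#'   \item{alpha (50)}{weight of the adipose density prior term. The prior
#'     term is dimensionless (a correlation), the data terms are in HU^2.}
#'   \item{beta (2000)}{weight of the contour-length (curvature) term.
#'     Because the data terms are squared HU differences, beta carries an
#'     HU^2 scale: 2000 = 0.2 x (100 HU)^2, with 100 HU the typical
#'     adipose-edema contrast. Tuned on the default phantom suite.}
#'   \item{epsilon (0.5)}{smoothing width of the regularized Heaviside, in
#'     phi units (pixels). A narrow band keeps the evolution close to the
#'     sharp-Heaviside energy and limits far-field leakage into the region
#'     means; tuned on the default phantom suite.}
#'   \item{dt (0.4)}{explicit time step of the evolution.}
#'   \item{maxIter (300), reinitEvery (20)}{iteration cap and signed-
#'     distance reinitialization period.}
#'   \item{convergeTol (1e-4)}{stop when the fraction of in-mask voxels
#'     whose phi sign changed in one iteration drops below this.}
#'   \item{nBins (64), histRange (-200, 100)}{histogram settings for the
#'     prior term; must match the fitted prior's histogram.}
#'   \item{priorMode ("dissimilarity")}{"dissimilarity" uses
#'     1 - correlation (0 when the adipose region matches the prior,
#'     growing with edema contamination, so the force shrinks as the
#'     outside region purifies); "literal_correlation" uses the raw
#'     correlation instead.}
#'   \item{initMode ("threshold")}{initial contour: the [-50, 50] HU window
#'     inside the mask ("threshold"), the GMM baseline labels ("gmm"), or a
#'     "checkerboard".}
#' }
#'
#' @param alpha,beta,epsilon,dt,maxIter,reinitEvery,convergeTol,nBins,histRange,priorMode,initMode
#'   see Description.
#' @return a [LevelSetParams-class].
#' @export
levelSetParams <- function(alpha = 50, beta = 2000, epsilon = 0.5, dt = 0.4,
                           maxIter = 300L, reinitEvery = 20L,
                           convergeTol = 1e-4, nBins = 64L,
                           histRange = c(-200, 100),
                           priorMode = c("dissimilarity",
                                         "literal_correlation"),
                           initMode = c("threshold", "gmm", "checkerboard")) {
  new("LevelSetParams", alpha = alpha, beta = beta, epsilon = epsilon,
      dt = dt, maxIter = as.integer(maxIter),
      reinitEvery = as.integer(reinitEvery), convergeTol = convergeTol,
      nBins = as.integer(nBins), histRange = as.numeric(histRange),
      priorMode = match.arg(priorMode), initMode = match.arg(initMode))
}

#' Regularized Heaviside and delta functions
#'
#' The sharp Heaviside of the energy (H(phi) = 1 if phi >= 0, else 0) is
#' replaced in the discrete evolution by the arctan regularization
#' \deqn{H_\epsilon(z) = \tfrac12\left(1 + \tfrac{2}{\pi}
#'   \arctan(z/\epsilon)\right), \qquad
#'   \delta_\epsilon(z) = \frac{1}{\pi}\,\frac{\epsilon}{\epsilon^2+z^2},}
#' which recovers the sharp H as epsilon tends to 0. `epsilon = 0` requests
#' the sharp Heaviside directly (and is an error for the delta, whose sharp
#' limit acts nowhere on a grid).
#'
#' @param z numeric, phi values.
#' @param epsilon smoothing width in phi units; >= 0 for the Heaviside,
#'   > 0 for the delta.
#' @return numeric of the same shape as `z`.
#' @examples
#' smoothedHeaviside(0, 1.5)    # 0.5
#' smoothedHeaviside(-0.1, 0)   # sharp: 0
#' smoothedDelta(0, 1.5) * pi * 1.5  # 1
#' @export
smoothedHeaviside <- function(z, epsilon) {
  stopifnot(epsilon >= 0)
  if (epsilon == 0) {
    out <- as.numeric(z >= 0)
    if (is.matrix(z)) dim(out) <- dim(z)
    return(out)
  }
  0.5 * (1 + (2 / pi) * atan(z / epsilon))
}

#' @rdname smoothedHeaviside
#' @export
smoothedDelta <- function(z, epsilon) {
  stopifnot(epsilon > 0)
  (1 / pi) * epsilon / (epsilon^2 + z^2)
}

## Boundary-replicated neighbor shifts. shiftDown(x)[i,j] == x[i-1,j] etc.,
## so central differences read (shiftUp - shiftDown)/2 along rows.
shiftDown <- function(x) x[c(1L, seq_len(nrow(x) - 1L)), , drop = FALSE]
shiftUp <- function(x) x[c(seq_len(nrow(x))[-1L], nrow(x)), , drop = FALSE]
shiftRight <- function(x) x[, c(1L, seq_len(ncol(x) - 1L)), drop = FALSE]
shiftLeft <- function(x) x[, c(seq_len(ncol(x))[-1L], ncol(x)), drop = FALSE]

#' Mean curvature of the level-set function
#'
#' The curvature term div(grad phi / |grad phi|) of the evolution equation,
#' discretized with central differences; |grad phi| is regularized by eta
#' inside the square root and boundary rows/columns are replicated.
#'
#' @param phi numeric matrix (>= 3x3).
#' @param eta regularization added under the gradient-norm square root.
#' @return numeric matrix of curvature values; ~ 1/R on a circle of
#'   radius R.
#' @export
curvature <- function(phi, eta = 1e-8) {
  stopifnot(nrow(phi) >= 3L, ncol(phi) >= 3L)
  gr <- (shiftUp(phi) - shiftDown(phi)) / 2
  gc <- (shiftLeft(phi) - shiftRight(phi)) / 2
  nrm <- sqrt(gr^2 + gc^2 + eta)
  nr <- gr / nrm
  nc <- gc / nrm
  (shiftUp(nr) - shiftDown(nr)) / 2 + (shiftLeft(nc) - shiftRight(nc)) / 2
}

signedDistance <- function(fg) {
  din <- EBImage::distmap(fg * 1)
  dout <- EBImage::distmap((1 - fg) * 1)
  as.matrix(din) - as.matrix(dout)
}

#' Initialize the level-set state
#'
#' Builds a seed edema region inside the adipose mask — the [-50, 50] HU
#' density window ("threshold"), the GMM baseline labels ("gmm"), or an
#' 8-pixel "checkerboard" — and sets phi to the signed Euclidean distance to
#' the seed boundary (positive inside the seed). Voxels outside the adipose
#' mask are clamped to minus the maximum distance and stay frozen throughout
#' the evolution. A degenerate seed (empty, or covering the whole mask)
#' falls back to the checkerboard with a warning.
#'
#' @param image a [DensityImage-class].
#' @param adiposeMask a [BinaryMask-class]; must be non-empty.
#' @param mode "threshold", "gmm" or "checkerboard".
#' @param gmm a fitted [TwoClassGMM-class]; required when `mode = "gmm"`.
#' @return a [LevelSetState-class] at iteration 0, with C1/C2 set to the
#'   sharp region means.
#' @export
initPhi <- function(image, adiposeMask,
                    mode = c("threshold", "gmm", "checkerboard"),
                    gmm = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(image, "DensityImage"), is(adiposeMask, "BinaryMask"))
  mv <- adiposeMask@values
  if (sum(mv) == 0L) stop("adipose mask is empty")
  iv <- image@values

  checker <- function() {
    r <- matrix(seq_len(nrow(iv)), nrow(iv), ncol(iv))
    cl <- matrix(seq_len(ncol(iv)), nrow(iv), ncol(iv), byrow = TRUE)
    (((r - 1) %/% 8L + (cl - 1) %/% 8L) %% 2L == 0L) & mv == 1
  }
  seed <- switch(mode,
    threshold = (iv >= -50 & iv <= 50) & mv == 1,
    gmm = {
      if (is.null(gmm)) stop("mode 'gmm' requires a fitted TwoClassGMM")
      classifyEdemaGMM(image, adiposeMask, gmm)@values == 1
    },
    checkerboard = checker())
  nSeed <- sum(seed)
  if (nSeed == 0L || nSeed == sum(mv)) {
    if (mode != "checkerboard") {
      warning("degenerate '", mode,
              "' seed region; falling back to checkerboard")
      seed <- checker()
    } else stop("checkerboard seed degenerate on this mask")
  }

  phi <- signedDistance(seed)
  phi[mv == 0] <- -max(abs(phi[mv == 1]))
  inSeed <- seed & mv == 1
  outSeed <- !seed & mv == 1
  new("LevelSetState", phi = phi,
      C1 = mean(iv[inSeed]), C2 = mean(iv[outSeed]),
      F = 0, iteration = 0L, energy = NA_real_)
}

#' Update the region means C1 and C2
#'
#' For fixed phi, the energy is minimized by setting C1 and C2 to the
#' (Heaviside-weighted) mean densities of the inside (edema) and outside
#' (adipose) regions:
#' \deqn{C_1 = \frac{\sum I\,H(\phi)}{\sum H(\phi)},\qquad
#'       C_2 = \frac{\sum I\,(1-H(\phi))}{\sum (1-H(\phi))},}
#' all sums restricted to the support mask. `epsilon = 0` gives the sharp
#' means.
#'
#' @param imageNs a [GrayscaleMask-class] (image restricted to the adipose
#'   compartment).
#' @param state a [LevelSetState-class].
#' @param epsilon Heaviside smoothing width (see [smoothedHeaviside()]).
#' @return named numeric `c(C1 = ..., C2 = ...)`.
#' @export
updateRegionMeans <- function(imageNs, state, epsilon = 0.5) {
  stopifnot(is(imageNs, "GrayscaleMask"), is(state, "LevelSetState"))
  supp <- imageNs@support@values == 1
  iv <- imageNs@values
  h <- smoothedHeaviside(state@phi, epsilon)
  mIn <- sum(h[supp]); mOut <- sum((1 - h)[supp])
  if (mIn == 0 || mOut == 0)
    stop("contour vanished: a region has zero mass on the support")
  c(C1 = sum((iv * h)[supp]) / mIn,
    C2 = sum((iv * (1 - h))[supp]) / mOut)
}

#' Evaluate the adipose density prior term F
#'
#' Builds the density histogram of the current adipose region — the support
#' voxels with phi < 0, i.e. the background of the contour — on the prior
#' histogram's bin grid, and compares it with the edema-free prior:
#' `1 - correlation` in "dissimilarity" mode (default), the raw normalized
#' correlation in "literal_correlation" mode. The result is the scalar F
#' used in both the energy and the evolution equation. A constant region
#' histogram (correlation undefined) yields 0 with a warning.
#'
#' @inheritParams updateRegionMeans
#' @param priorHist the prior [DensityHistogram-class].
#' @param params a [LevelSetParams-class].
#' @return a scalar: in [0, 2] ("dissimilarity") or [-1, 1]
#'   ("literal_correlation").
#' @export
computePriorTerm <- function(imageNs, state, priorHist, params) {
  stopifnot(is(priorHist, "DensityHistogram"))
  supp <- imageNs@support@values == 1
  bg <- supp & state@phi < 0
  if (!any(bg))
    stop("empty background: no support voxels with phi < 0")
  edges <- priorHist@binEdges
  h <- buildHistogram(imageNs@values[bg],
                      nBins = length(edges) - 1L,
                      range = c(edges[1], edges[length(edges)]))
  if (histVariance(h) == 0) {
    warning("zero-variance background histogram; prior term set to 0")
    return(0)
  }
  ncc <- normalizedCorrelation(h, priorHist)
  if (params@priorMode == "dissimilarity") 1 - ncc else ncc
}

#' One explicit evolution step
#'
#' Advances phi by one explicit Euler step of the evolution equation
#' \deqn{\frac{\partial\phi}{\partial t} = \delta_\epsilon(\phi)\left[
#'   -(I-C_1)^2 + (I-C_2)^2 + \alpha F
#'   + \beta\,\mathrm{div}\!\left(\frac{\nabla\phi}{|\nabla\phi|}\right)
#'   \right]}
#' on the support (phi is frozen outside). C1 and C2 are taken from the
#' state and must be current (apply [updateRegionMeans()] first); F is
#' recomputed from the current phi < 0 region before the update whenever
#' `alpha > 0` and a prior histogram is supplied, and is applied as a
#' spatially uniform scalar force.
#'
#' @inheritParams computePriorTerm
#' @param priorHist the prior [DensityHistogram-class], or NULL to drop the
#'   prior term (plain two-phase evolution).
#' @return the advanced [LevelSetState-class] (iteration incremented, F
#'   stored).
#' @export
evolveStep <- function(state, imageNs, priorHist = NULL, params) {
  stopifnot(is(state, "LevelSetState"), is(imageNs, "GrayscaleMask"),
            is(params, "LevelSetParams"))
  supp <- imageNs@support@values == 1
  Fval <- if (params@alpha > 0 && !is.null(priorHist))
    computePriorTerm(imageNs, state, priorHist, params) else 0
  iv <- imageNs@values
  phi <- state@phi
  force <- -(iv - state@C1)^2 + (iv - state@C2)^2 + params@alpha * Fval +
    params@beta * curvature(phi)
  upd <- params@dt * smoothedDelta(phi, params@epsilon) * force
  phi[supp] <- phi[supp] + upd[supp]
  if (any(!is.finite(phi[supp])))
    stop("non-finite level set update; dt is too large for this image")
  new("LevelSetState", phi = phi, C1 = state@C1, C2 = state@C2, F = Fval,
      iteration = state@iteration + 1L, energy = state@energy)
}

#' Evaluate the segmentation energy
#'
#' The discrete energy
#' \deqn{E = \sum_{\mathrm{support}}\Big\{(I-C_1)^2 H_\epsilon(\phi)
#'   + \big[(I-C_2)^2 + \alpha F\big](1-H_\epsilon(\phi))
#'   + \beta\,|\nabla H_\epsilon(\phi)|\Big\}}
#' with the smoothed Heaviside and central-difference gradients. F is
#' recomputed from the current phi < 0 region when `alpha > 0` and a prior
#' histogram is given.
#'
#' @inheritParams evolveStep
#' @return a scalar energy value.
#' @export
computeEnergy <- function(state, imageNs, priorHist = NULL, params) {
  supp <- imageNs@support@values == 1
  iv <- imageNs@values
  h <- smoothedHeaviside(state@phi, params@epsilon)
  Fval <- if (params@alpha > 0 && !is.null(priorHist))
    computePriorTerm(imageNs, state, priorHist, params) else 0
  gr <- (shiftUp(h) - shiftDown(h)) / 2
  gc <- (shiftLeft(h) - shiftRight(h)) / 2
  gradH <- sqrt(gr^2 + gc^2)
  sum(((iv - state@C1)^2 * h)[supp]) +
    sum((((iv - state@C2)^2 + params@alpha * Fval) * (1 - h))[supp]) +
    params@beta * sum(gradH[supp])
}

#' Reinitialize phi to a signed distance function
#'
#' Replaces phi by the signed Euclidean distance to its current zero level
#' set (distance transforms of the phi >= 0 region and its complement); the
#' sign pattern is preserved exactly. Periodic reinitialization keeps
#' |grad phi| near 1, which the curvature and delta terms assume.
#'
#' @param phi numeric matrix with both signs present.
#' @return a signed distance matrix with the same sign pattern.
#' @export
reinitialize <- function(phi) {
  fg <- phi >= 0
  if (all(fg) || !any(fg))
    stop("contour vanished: phi has a single sign, cannot reinitialize")
  signedDistance(fg)
}

#' Run the full prior-constrained level-set segmentation of one slice
#'
#' Alternates the mean updates, the prior term and the evolution step, with
#' periodic signed-distance reinitialization, until the fraction of in-mask
#' voxels whose phi sign changed in one iteration drops below
#' `params@convergeTol` (or `maxIter` is reached). The returned edema mask
#' is the phi >= 0 region intersected with the adipose mask. If the contour
#' vanishes (phi becomes single-signed on the mask), an empty edema mask is
#' returned with `vanished = TRUE`.
#'
#' @param image a [DensityImage-class].
#' @param adiposeMask a [BinaryMask-class] of the same shape.
#' @param prior a [PriorModel-class] (may be NULL when `params@alpha == 0`).
#' @param params a [LevelSetParams-class].
#' @return a list with elements `mask` ([BinaryMask-class]), `trace` (a
#'   data.frame with columns iter, C1, C2, F, energy, changed_frac; the
#'   iter-0 row records the freshly initialized state),
#'   `state` (final [LevelSetState-class]), `converged` and `vanished`
#'   (logical flags).
#' @examples
#' sm <- generatePhantom(phantomSpec(gridSize = 96L, ringInner = 26,
#'                                   ringOuter = 40, edemaBlobCount = 2L,
#'                                   blobRadiusRange = c(3, 6)), seed = 2)
#' pr <- fitPrior(generateTrainingPairs(sm@spec, n = 2, seed = 3))
#' res <- runSegmentation(sm@image, sm@adiposeMask, pr,
#'                        levelSetParams(maxIter = 60L))
#' sum(pixelValues(res$mask))
#' @export
runSegmentation <- function(image, adiposeMask, prior,
                            params = levelSetParams()) {
  stopifnot(is(image, "DensityImage"), is(adiposeMask, "BinaryMask"),
            is(params, "LevelSetParams"))
  if (params@alpha > 0 && is.null(prior))
    stop("alpha > 0 requires a fitted PriorModel")
  imageNs <- applyMask(image, adiposeMask)
  priorHist <- if (is.null(prior)) NULL else prior@histogram
  gmm <- if (params@initMode == "gmm")
    fitGMM(maskedValues(imageNs)) else NULL
  state <- initPhi(image, adiposeMask, mode = params@initMode, gmm = gmm)

  supp <- adiposeMask@values == 1
  nSupp <- sum(supp)
  emptyResult <- function(state, trace, converged) {
    list(mask = binaryMask(matrix(0, nrow(image@values), ncol(image@values))),
         trace = trace, state = state, converged = converged, vanished = TRUE)
  }
  state@energy <- computeEnergy(state, imageNs, priorHist, params)
  trace <- data.frame(iter = 0L, C1 = state@C1, C2 = state@C2, F = state@F,
                      energy = state@energy, changed_frac = NA_real_)
  converged <- FALSE
  for (it in seq_len(params@maxIter)) {
    signBefore <- state@phi[supp] >= 0
    if (all(signBefore) || !any(signBefore))
      return(emptyResult(state, trace, converged))
    m <- updateRegionMeans(imageNs, state, epsilon = params@epsilon)
    state@C1 <- m[["C1"]]; state@C2 <- m[["C2"]]
    state <- evolveStep(state, imageNs, priorHist, params)
    if (it %% params@reinitEvery == 0L) {
      signs <- state@phi[supp] >= 0
      if (all(signs) || !any(signs))
        return(emptyResult(state, trace, converged))
      state@phi <- reinitialize(state@phi)
      state@phi[!supp] <- -max(abs(state@phi[supp]))
    }
    changed <- mean((state@phi[supp] >= 0) != signBefore)
    state@energy <- computeEnergy(state, imageNs, priorHist, params)
    trace <- rbind(trace, data.frame(
      iter = it, C1 = state@C1, C2 = state@C2, F = state@F,
      energy = state@energy, changed_frac = changed))
    if (changed < params@convergeTol && it > 1L) { converged <- TRUE; break }
  }
  mask <- binaryMask((state@phi >= 0 & supp) * 1)
  list(mask = mask, trace = trace, state = state, converged = converged,
       vanished = FALSE)
}

setMethod("show", "LevelSetState", function(object) {
  cat(sprintf(
    "LevelSetState | iter %d | C1 %.1f HU | C2 %.1f HU | F %.4f | %d voxels inside\n",
    object@iteration, object@C1, object@C2, object@F,
    sum(object@phi >= 0)))
})

setMethod("show", "LevelSetParams", function(object) {
  cat(sprintf(
    paste0("LevelSetParams | alpha %g beta %g | eps %g dt %g | maxIter %d ",
           "reinit %d tol %g | %d bins [%g, %g] | %s / %s init\n"),
    object@alpha, object@beta, object@epsilon, object@dt, object@maxIter,
    object@reinitEvery, object@convergeTol, object@nBins,
    object@histRange[1], object@histRange[2], object@priorMode,
    object@initMode))
})
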