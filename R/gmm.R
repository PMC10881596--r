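#' Fit a two-class Gaussian mixture to adipose-compartment densities
#'
#' The baseline density model: the HU values inside the subcutaneous adipose
#' compartment are modelled as a mixture of two Gaussians — adipose tissue
#' (low HU) and edema fluid (near-water HU) — fitted by expectation-
#' maximization. Initialization is deterministic: the values are split at
#' their median and each half supplies the initial moments of one component,
#' which removes seed sensitivity from the baseline. Component standard
#' deviations are floored at `sigmaFloor`; a component that collapses onto
#' the floor while its weight drops below `wFloor` is reported as a
#' degenerate fit. On return components are ordered so that the second
#' (higher-mean) component is the edema class.
#'
#' @param values numeric vector of HU densities (>= 20 values).
#' @param tol EM stops when the log-likelihood gain drops below this.
#' @param maxIter iteration cap.
#' @param seed accepted for interface symmetry with the stochastic parts of
#'   the package; the deterministic initialization makes it inert.
#' @param sigmaFloor,wFloor degeneracy guards (HU and weight).
#' @return a [TwoClassGMM-class].
#' @examples
#' set.seed(1)
#' v <- c(rnorm(500, -100, 15), rnorm(500, 0, 15))
#' fitGMM(v)
#' @export
fitGMM <- function(values, tol = 1e-6, maxIter = 500L, seed = NULL,
                   sigmaFloor = 0.5, wFloor = 0.01) {
  if (length(values) < 20L) stop("need at least 20 values to fit the mixture")
  stopifnot(tol > 0)
  if (stats::sd(values) == 0)
    stop("degenerate fit: all values identical")
  med <- stats::median(values)
  lo <- values[values <= med]; hi <- values[values > med]
  if (length(hi) == 0L) { hi <- lo }  # heavily tied data; same init both sides
  mu <- c(mean(lo), mean(hi))
  sg <- pmax(c(stats::sd(lo), stats::sd(hi)), sigmaFloor)
  sg[is.na(sg)] <- sigmaFloor
  w <- c(0.5, 0.5)

  ll <- -Inf; trace <- numeric(0)
  for (it in seq_len(maxIter)) {
    d1 <- w[1] * stats::dnorm(values, mu[1], sg[1])
    d2 <- w[2] * stats::dnorm(values, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    newLL <- sum(log(tot))
    # EM guarantees monotone log-likelihood; allow rounding-level slack
    if (length(trace) && newLL < trace[length(trace)] - 1e-8)
      stop("internal error: log-likelihood decreased during EM")
    trace <- c(trace, newLL)
    r1 <- d1 / tot
    n1 <- sum(r1); n2 <- length(values) - n1
    if (n1 / length(values) < wFloor || n2 / length(values) < wFloor)
      stop("degenerate fit: a mixture component collapsed (weight < ",
           wFloor, ")")
    w <- c(n1, n2) / length(values)
    mu <- c(sum(r1 * values) / n1, sum((1 - r1) * values) / n2)
    sg <- sqrt(c(sum(r1 * (values - mu[1])^2) / n1,
                 sum((1 - r1) * (values - mu[2])^2) / n2))
    collapsed <- sg < sigmaFloor
    if (any(collapsed & w < wFloor))
      stop("degenerate fit: component variance collapsed below the floor")
    sg <- pmax(sg, sigmaFloor)
    if (is.finite(ll) && newLL - ll < tol) { ll <- newLL; break }
    ll <- newLL
  }
  ord <- order(mu)  # adipose first, edema (higher mean) second
  new("TwoClassGMM", weights = w[ord], means = mu[ord], stds = sg[ord],
      logLik = ll, nIter = length(trace), llTrace = trace)
}

#' Posterior probability of the edema component
#'
#' @param gmm a [TwoClassGMM-class].
#' @param values numeric vector of HU densities.
#' @return numeric vector of posterior probabilities that each value belongs
#'   to the higher-mean (edema) component.
#' @export
edemaPosterior <- function(gmm, values) {
  stopifnot(is(gmm, "TwoClassGMM"))
  d1 <- gmm@weights[1] * stats::dnorm(values, gmm@means[1], gmm@stds[1])
  d2 <- gmm@weights[2] * stats::dnorm(values, gmm@means[2], gmm@stds[2])
  tot <- d1 + d2
  # far in the tails both densities underflow; decide by the nearer mean
  far <- tot == 0
  p <- d2 / ifelse(far, 1, tot)
  if (any(far))
    p[far] <- as.numeric(abs(values[far] - gmm@means[2]) / gmm@stds[2] <
                         abs(values[far] - gmm@means[1]) / gmm@stds[1])
  p
}

#' Segment edema with the GMM baseline
#'
#' Labels a voxel as edema iff it lies inside the adipose compartment and
#' its posterior probability under the higher-mean (edema) component is at
#' least 0.5 — the maximum a posteriori rule. Voxels outside the mask are
#' never labeled.
#'
#' @param image a [DensityImage-class].
#' @param adiposeMask a [BinaryMask-class] of the same shape.
#' @param gmm a [TwoClassGMM-class] fitted on this image's masked values (or
#'   compatible data).
#' @return a [BinaryMask-class] of edema voxels.
#' @seealso [fitGMM()], [runSegmentation()]
#' @export
classifyEdemaGMM <- function(image, adiposeMask, gmm) {
  stopifnot(is(image, "DensityImage"), is(adiposeMask, "BinaryMask"))
  iv <- image@values; mv <- adiposeMask@values
  if (!identical(dim(iv), dim(mv))) stop("shape mismatch")
  lab <- matrix(0, nrow(iv), ncol(iv))
  inside <- mv == 1
  lab[inside] <- as.numeric(edemaPosterior(gmm, iv[inside]) >= 0.5)
  binaryMask(lab)
}

setMethod("show", "TwoClassGMM", function(object) {
  cat(sprintf(
    paste0("TwoClassGMM | adipose %.1f +/- %.1f HU (w=%.2f) | ",
           "edema %.1f +/- %.1f HU (w=%.2f) | logLik %.1f in %d iter\n"),
    object@means[1], object@stds[1], object@weights[1],
    object@means[2], object@stds[2], object@weights[2],
    object@logLik, object@nIter))
})
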