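# Independent reference implementations used as oracles. Each is coded
# directly from the mathematical definition, separately from the package
# internals (loops / padded arrays instead of the package's shift helpers).

# normalized correlation of two count vectors, by explicit loops
oracleNCC <- function(g1, g2) {
  n <- length(g1)
  m1 <- 0; m2 <- 0
  for (i in seq_len(n)) { m1 <- m1 + g1[i]; m2 <- m2 + g2[i] }
  m1 <- m1 / n; m2 <- m2 / n
  num <- 0; v1 <- 0; v2 <- 0
  for (i in seq_len(n)) {
    num <- num + (g1[i] - m1) * (g2[i] - m2)
    v1 <- v1 + (g1[i] - m1)^2
    v2 <- v2 + (g2[i] - m2)^2
  }
  num / sqrt(v1 * v2)
}

# histogram counts on a uniform grid, by explicit loop (clip + left-closed
# bins, last closed)
oracleHistCounts <- function(values, nBins, lo, hi) {
  counts <- numeric(nBins)
  width <- (hi - lo) / nBins
  for (v in values) {
    v <- min(max(v, lo), hi)
    b <- floor((v - lo) / width) + 1
    if (b > nBins) b <- nBins
    # guard against floating division landing one bin high at an edge
    while (b > 1 && v < lo + (b - 1) * width) b <- b - 1
    counts[b] <- counts[b] + 1
  }
  counts
}

# region means by direct weighted sums over the support
oracleRegionMeans <- function(img, phi, supp, eps) {
  n1 <- 0; d1 <- 0; n2 <- 0; d2 <- 0
  for (j in seq_len(ncol(img))) for (i in seq_len(nrow(img))) {
    if (!supp[i, j]) next
    h <- if (eps == 0) as.numeric(phi[i, j] >= 0)
         else 0.5 * (1 + (2 / pi) * atan(phi[i, j] / eps))
    n1 <- n1 + img[i, j] * h;       d1 <- d1 + h
    n2 <- n2 + img[i, j] * (1 - h); d2 <- d2 + (1 - h)
  }
  c(n1 / d1, n2 / d2)
}

# curvature div(grad phi / |grad phi|) by per-pixel central differences with
# replicated boundaries
oracleCurvature <- function(phi, eta = 1e-8) {
  n <- nrow(phi); m <- ncol(phi)
  at <- function(i, j) phi[min(max(i, 1), n), min(max(j, 1), m)]
  gr <- matrix(0, n, m); gc <- matrix(0, n, m)
  for (j in seq_len(m)) for (i in seq_len(n)) {
    gr[i, j] <- (at(i + 1, j) - at(i - 1, j)) / 2
    gc[i, j] <- (at(i, j + 1) - at(i, j - 1)) / 2
  }
  nm <- sqrt(gr^2 + gc^2 + eta)
  nr <- gr / nm; nc <- gc / nm
  atm <- function(mm, i, j) mm[min(max(i, 1), n), min(max(j, 1), m)]
  k <- matrix(0, n, m)
  for (j in seq_len(m)) for (i in seq_len(n)) {
    k[i, j] <- (atm(nr, i + 1, j) - atm(nr, i - 1, j)) / 2 +
               (atm(nc, i, j + 1) - atm(nc, i, j - 1)) / 2
  }
  k
}

# one explicit step of the evolution PDE, everything recomputed directly:
# F from the phi<0 region histogram vs the prior, then
# phi <- phi + dt * delta(phi) * (-(I-C1)^2 + (I-C2)^2 + alpha F + beta kappa)
oraclePDEStep <- function(phi, img, supp, C1, C2, priorCounts, edges,
                          alpha, beta, dt, eps) {
  Fval <- 0
  if (alpha > 0) {
    bg <- img[supp & phi < 0]
    counts <- oracleHistCounts(bg, length(priorCounts), edges[1],
                               edges[length(edges)])
    Fval <- 1 - oracleNCC(counts, priorCounts)
  }
  kap <- oracleCurvature(phi)
  out <- phi
  for (j in seq_len(ncol(phi))) for (i in seq_len(nrow(phi))) {
    if (!supp[i, j]) next
    z <- phi[i, j]
    dlt <- (1 / pi) * eps / (eps^2 + z^2)
    force <- -(img[i, j] - C1)^2 + (img[i, j] - C2)^2 + alpha * Fval +
      beta * kap[i, j]
    out[i, j] <- z + dt * dlt * force
  }
  list(phi = out, F = Fval)
}

# plain two-phase Chan-Vese (no prior term), coded from the model with
# padded-array finite differences; same discretization parameters as the
# package but an independent code path
oraclePlainChanVese <- function(img, mask, beta, eps, dt, maxIter,
                                reinitEvery, tol) {
  pad <- function(m) {
    n <- nrow(m); k <- ncol(m)
    p <- matrix(0, n + 2, k + 2)
    p[2:(n + 1), 2:(k + 1)] <- m
    p[1, ] <- p[2, ]; p[n + 2, ] <- p[n + 1, ]
    p[, 1] <- p[, 2]; p[, k + 2] <- p[, k + 1]
    p
  }
  ddr <- function(m) { p <- pad(m); n <- nrow(m); k <- ncol(m)
    (p[3:(n + 2), 2:(k + 1)] - p[1:n, 2:(k + 1)]) / 2 }
  ddc <- function(m) { p <- pad(m); n <- nrow(m); k <- ncol(m)
    (p[2:(n + 1), 3:(k + 2)] - p[2:(n + 1), 1:k]) / 2 }
  kappa <- function(phi) {
    gr <- ddr(phi); gc <- ddc(phi)
    nm <- sqrt(gr^2 + gc^2 + 1e-8)
    ddr(gr / nm) + ddc(gc / nm)
  }
  sdist <- function(fg) {
    as.matrix(EBImage::distmap(fg * 1)) -
      as.matrix(EBImage::distmap((1 - fg) * 1))
  }
  H <- function(z) 0.5 * (1 + (2 / pi) * atan(z / eps))
  delta <- function(z) (1 / pi) * eps / (eps^2 + z^2)

  s <- mask == 1
  seed <- (img >= -50 & img <= 50) & s
  phi <- sdist(seed)
  phi[!s] <- -max(abs(phi[s]))
  for (it in seq_len(maxIter)) {
    before <- phi[s] >= 0
    if (all(before) || !any(before)) break
    h <- H(phi)
    c1 <- sum((img * h)[s]) / sum(h[s])
    c2 <- sum((img * (1 - h))[s]) / sum((1 - h)[s])
    force <- -(img - c1)^2 + (img - c2)^2 + beta * kappa(phi)
    phi[s] <- phi[s] + (dt * delta(phi) * force)[s]
    if (it %% reinitEvery == 0L) {
      sg <- phi[s] >= 0
      if (all(sg) || !any(sg)) break
      phi <- sdist(phi >= 0)
      phi[!s] <- -max(abs(phi[s]))
    }
    if (mean((phi[s] >= 0) != before) < tol && it > 1L) break
  }
  (phi >= 0 & s) * 1
}
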