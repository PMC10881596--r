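---
title: "Subcutaneous edema segmentation: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subcutaneous edema segmentation: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edemaCV)
```

## The problem and the density model

Subcutaneous edema is fluid retention inside the adipose compartment
between skin and muscle wall. On CT, healthy subcutaneous fat is
homogeneous with strongly negative density (around −100 HU), while edema
fluid sits near water (around 0 HU) and is diffused through the fat as
heterogeneous, discontinuous pockets without sharp boundaries. The density
of the masked compartment is therefore well described as a two-class
mixture — an adipose Gaussian plus an edema class inside roughly
[−50, 50] HU — and that observation drives everything in this package:

* the **baseline** fits exactly that two-class Gaussian mixture by EM and
  labels each voxel by maximum posterior (`fitGMM()`,
  `classifyEdemaGMM()`);
* the **main method** embeds the density model into a Chan-Vese level set,
  where a histogram prior built from *edema-free* adipose tissue supplies
  a global force that keeps the contour evolving until the adipose side of
  the partition is free of the second (edema) mode
  (`runSegmentation()`).

The adipose mask itself is an *input* (in practice produced by an upstream
adipose segmentor; here by the phantom generator): everything — region
means, histograms, the evolution — is computed strictly on its support.
Because edema densities straddle 0 HU, a zero pixel value is not evidence
of background; `GrayscaleMask` therefore carries its support mask
explicitly, and no statistic in the package ever tests values against
zero to decide membership.

## The energy and its discretization

The segmentation minimizes, over the support,

$$E = \sum (I-C_1)^2 H(\phi) + \left[(I-C_2)^2 + \alpha F\right](1-H(\phi))
      + \beta\,|\nabla H(\phi)|$$

with $\phi$ a signed distance function, $C_1, C_2$ the inside/outside mean
densities, and $F$ the histogram prior term. The definition of $H$ is
sharp ($H(\phi)=1$ iff $\phi \ge 0$; ties count as inside, which also fixes
the tie-break in every mask produced from $\phi$). A sharp delta acts
nowhere on a discrete grid, so the evolution uses the standard arctan
regularization
$H_\epsilon(z)=\tfrac12(1+\tfrac2\pi\arctan(z/\epsilon))$,
$\delta_\epsilon = H_\epsilon'$, and alternates:

1. closed-form mean updates $C_1, C_2$ (Heaviside-weighted means on the
   support);
2. recomputation of $F$ from the current $\{\phi<0\}$ region;
3. one explicit Euler step
   $\phi \leftarrow \phi + \Delta t\,\delta_\epsilon(\phi)
   [-(I-C_1)^2+(I-C2)^2+\alpha F+\beta\,\mathrm{div}(\nabla\phi/|\nabla\phi|)]$;
4. every `reinitEvery` iterations, reinitialization of $\phi$ to the
   signed Euclidean distance of its own sign pattern (distance transforms;
   sign-preserving by construction).

$\phi$ is frozen outside the adipose mask and clamped negative there, so
the contour can never leave the compartment; the final mask is
$\{\phi \ge 0\}$ intersected with the mask. Evolution is strictly 2D per
slice; scans are handled by `segmentScan()`, which composes independent
per-slice results — there is no 3D PDE.

### The prior term

$F$ compares the density histogram of the current adipose region with the
prior histogram by mean-centred normalized correlation (Cauchy–Schwarz
bounds it to $[-1,1]$; mean-centring makes it invariant to positive affine
rescaling of counts, so raw counts are used without density
normalization). Two runtime-selectable forms are exposed because the
correlation itself is maximal when the histograms *match*, while the
intended behaviour of the constraint is to be *minimal* for pure adipose
tissue and large under edema contamination:

* `"dissimilarity"` (default): $F = 1 - \mathrm{corr} \in [0, 2]$, zero
  exactly when the region histogram matches the edema-free prior. As a
  positive, spatially uniform force scaled by $\alpha$ it pushes the
  contour outward while contamination persists and fades as the adipose
  region purifies — the stated minimal/maximal behaviour.
* `"literal_correlation"`: the raw correlation, for users who want the
  untransformed algebraic form.

Whether the original constraint was meant per-iteration or per-checkpoint,
and regional or global, is not specified anywhere we could follow; this
implementation recomputes $F$ on every iteration from the full $\phi<0$
region and applies it as a global scalar, the most literal reading of the
evolution equation. A constant (zero-variance) region histogram leaves the
correlation undefined; the term then falls back to 0 with a warning rather
than aborting a nearly converged run.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `alpha` | 50 | HU² per unit of F | weight of the (dimensionless) prior term against squared-HU data terms |
| `beta` | 2000 | HU² | curvature/length weight; 0.2 × (100 HU)², with 100 HU the typical adipose–edema contrast |
| `epsilon` | 0.5 | pixels (φ units) | Heaviside/delta smoothing width |
| `dt` | 0.4 | — | explicit time step |
| `maxIter` / `reinitEvery` | 300 / 20 | iterations | cap and reinitialization period |
| `convergeTol` | 1e-4 | fraction | stop when fewer than this fraction of in-mask voxels change sign per iteration |
| `nBins`, `histRange` | 64, [−200, 100] HU | — | histogram grid; covers fat and fluid densities. Unstated upstream; fixed here once |
| `priorMode`, `initMode` | dissimilarity, threshold | — | see above / below |

`beta` and `epsilon` were tuned once on the default phantom suite (the
package's own calibration set) and then frozen; both are fully exposed. A
narrow `epsilon` keeps the evolution close to the sharp-Heaviside energy
and limits the leakage of far-field voxels into the Heaviside-weighted
region means — with wide smoothing, thousands of adipose voxels each
contribute a few percent of membership to the edema mean and bias it
noticeably.

Initialization is not specified by the method's formulation, so three
modes are provided: the [−50, 50] HU window inside the mask (default —
cheap, close to the annotation protocol, and a good starting contour), the
GMM baseline labels, and a 50/50 checkerboard for a fully agnostic start.
A degenerate seed (empty, or the entire mask) falls back to the
checkerboard with a warning. The stopping rule (changed-sign fraction) is
likewise a package decision; the trace returned by `runSegmentation()`
records C1, C2, F, energy and the changed fraction per iteration so any
other rule can be audited after the fact.

Numerical details: curvature uses central differences of the normalized
gradient with `1e-8` regularization under the square root and replicated
borders; a non-finite update aborts with a pointer at `dt`; a vanished
contour (single-signed φ) returns an empty edema mask with a flag rather
than an error, since "no edema" is a legitimate clinical finding.

## The GMM baseline

EM on the masked densities with deterministic initialization (median
split, component moments from each half), which removes seed sensitivity
from the baseline. Standard deviations are floored at 0.5 HU and a
component collapsing onto the floor with weight below 0.01 is reported as
degenerate rather than silently inverted. The exact voxel rule of the
original baseline ("within the edema density distribution") is not
restated anywhere in reach, so the canonical maximum-a-posteriori reading
(posterior of the higher-mean component ≥ 0.5) is implemented and
documented as such. Log-likelihood monotonicity is asserted at every
step.

## What the phantoms emulate — and what they do not

`generatePhantom()` builds the density structure the method assumes: an
annular subcutaneous fat compartment with near-Gaussian density
(−100 ± 15 HU by default), edema blobs as unions of jittered overlapping
discs (mimicking heterogeneous, discontinuous shape) whose densities are
truncated into the [−50, 50] HU annotation window, additive global
acquisition noise (5 HU), and exact ground-truth masks. Defaults are
fixture parameters chosen once for plausibility — fat and fluid separated
the way the two-class mixture assumes — not measurements of real tissue;
real-data statistics beyond the annotation window were not available to
copy. The generator deliberately omits organs, bone, contrast phases,
scanner artifacts, partial-volume gradients at the fascia, and any
correlation structure in the noise. Passing the suite therefore
demonstrates the *mechanics* of the methods (recovery under the assumed
density model, regularization behaviour, metric correctness), not clinical
accuracy; on real scans both methods face overlap and texture this
generator does not produce, and reported accuracies here are accordingly
much higher than anything achievable on patients.

Training pairs for the prior are edema-free phantoms restricted to their
masks — a desk-scale stand-in for a pool of real edema-free subjects. The
statistical prior generator (`generatePriorMask()`) plays the functional
role of a learned mask-to-texture network: a network trained on edema-free
subjects generates edema-free texture for any input mask; the surrogate
achieves the same contract by sampling the fitted Gaussian. The interface
accepts externally generated masks (`externalPriorMask()`) so a trained
generator can be slotted in without code change.

One deliberate scale choice: sample sizes in tests and the acceptance
script (20-phantom suites, 5 training pairs, 10⁴-draw recovery checks) are
the package's validation conditions — large enough for the law-of-large-
numbers checks they carry, small enough that the whole suite runs in
seconds.

## Evaluation conventions

* [−50, 50] HU annotation window: bounds inclusive on both ends,
  following the bracket notation of the protocol. Only the reproducible
  thresholding + masking stages are implemented; the manual editing stage
  of the full protocol is a human step.
* Volumes from voxel geometry: count × pixel area × slice thickness
  (mm³), converted to litres (×10⁻⁶); AVD is a volume difference, not an
  overlap measure, so disjoint equal-volume masks score AVD = 0 with
  IoU = DSC = 0.
* Metrics pool voxel counts over the slices of one scan; across scans the
  convention is per-scan averaging (as in the acceptance script). Both
  conventions are trivially available from the per-slice table in
  `MetricsReport`.
* Two empty masks agree perfectly (100%); RVD against an empty reference
  is undefined and reported as `NA`.

## Known limitations

2D-per-slice evolution only; a single global prior force (no spatial
localization of F, so the prior cannot by itself steer *where* the contour
grows); no DICOM series reading, resampling or registration; the C-GAN and
adipose-segmentor networks of the full clinical pipeline are out of scope
— their contracts are represented by the prior-generator interface and the
mask input respectively. The 16-bit PNG writer encodes grayscale,
unpaletted, non-interlaced images only, which is all the sidecar format
specifies.
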