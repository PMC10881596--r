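# edemaCV

Segmentation and volume measurement of **subcutaneous edema on abdominal
CT**. Edema — fluid retention in tissue, common in kidney, heart and liver
disease — appears on CT as heterogeneous near-water densities (around 0 HU)
diffused inside the subcutaneous fat compartment (around −100 HU). Unlike a
tumour or an organ it is discontinuous, highly variable in shape and has no
clear boundary, which makes supervised annotation (and hence deep
segmentation models) difficult. This package is for image-analysis
researchers and clinical-imaging scientists who need an unsupervised,
density-model-based edema segmentation together with the tooling to
validate it: synthetic phantoms with exact ground truth, the classical
mixture-model baseline, and the standard accuracy metrics.

## The model

Given a CT slice `I` and a binary subcutaneous adipose mask, the masked
grayscale image `I_ns` is segmented by a Chan-Vese level set `φ` (signed
distance function; `φ ≥ 0` = edema, `φ < 0` = adipose) minimizing

```
E = ∫ (I_ns − C1)² H(φ) + [ (I_ns − C2)² + α F ] (1 − H(φ)) + β |∇H(φ)| dx
```

where `C1`, `C2` are the mean densities of the edema and adipose regions
and `H` the Heaviside function. The distinguishing term is the **adipose
density prior** `F`: the density histogram `G` of the current adipose
region (`φ < 0`) is compared by normalized correlation

```
F = Σ (G_region − Ḡ_region)(G_prior − Ḡ_prior)
    ─────────────────────────────────────────────
    √[ Σ (G_region − Ḡ_region)² Σ (G_prior − Ḡ_prior)² ]
```

with the histogram of an *edema-free* adipose reference (in dissimilarity
form, `1 − F`, the term vanishes only when the adipose region is free of
edema contamination, so it keeps the contour moving until the fluid is
separated out). The reference is produced by a pluggable prior generator:
the built-in statistical surrogate fills the mask with densities from a
Gaussian model fitted on edema-free training pairs, and externally
generated masks (e.g. from a trained mask-to-texture network) can be
slotted in via `externalPriorMask()`. Minimization alternates closed-form
mean updates with the explicit evolution

```
∂φ/∂t = δ(φ) [ −(I_ns − C1)² + (I_ns − C2)² + α F + β div(∇φ/|∇φ|) ]
```

The baseline it is compared against fits a **two-class Gaussian mixture**
(adipose vs edema) to the masked densities by EM and labels voxels by
maximum posterior. Accuracy is reported as IoU, Dice (DSC), absolute volume
difference (AVD, litres) and relative volume difference (RVD).

## Worked example

```r
library(edemaCV)

spec   <- phantomSpec()                       # 256x256 adipose ring + edema blobs
sample <- generatePhantom(spec, seed = 7)
sample
#> PhantomSample (seed 7) | 256x256 | adipose 17916 vox | edema 1218 vox

prior <- fitPrior(generateTrainingPairs(spec, n = 5, seed = 101))
prior
#> PriorModel | adipose -99.9 +/- 15.8 HU | 64-bin histogram | edema-free adipose training pairs

res <- runSegmentation(sample@image, sample@adiposeMask, prior)
computeMetrics(res$mask, sample@edemaMask, spacing = c(1, 1), thickness = 5)
#> MetricsReport | IoU 100.0% | DSC 100.0% | AVD 0.0000 L | RVD 0.0% | 1 slice(s)

gmm <- fitGMM(maskedValues(applyMask(sample@image, sample@adiposeMask)))
gmm
#> TwoClassGMM | adipose -100.0 +/- 15.9 HU (w=0.93) | edema 0.0 +/- 15.9 HU (w=0.07) | logLik -79413.0 in 28 iter
computeMetrics(classifyEdemaGMM(sample@image, sample@adiposeMask, gmm),
               sample@edemaMask, spacing = c(1, 1), thickness = 5)
#> MetricsReport | IoU 99.4% | DSC 99.7% | AVD 0.0000 L | RVD 0.2% | 1 slice(s)
```

The phantom's edema blobs carry densities in the [−50, 50] HU annotation
window inside a −100 ± 15 HU adipose ring, so both methods do well; the
level set additionally regularizes away isolated noise voxels that the
voxel-wise mixture rule mislabels, which is where its advantage over the
baseline comes from (here: a perfect recovery vs 99.7% DSC).

A command-line wrapper for phantom generation, prior fitting, both
segmentation methods and evaluation is installed at
`inst/scripts/edemacv.R` (run `Rscript edemacv.R <subcommand> ...`; see the
header comment for usage). Images and masks are exchanged as NIfTI or
16-bit PNG + JSON sidecar.

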