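---
title: "Methods: tissue-signature segmentation and lesion classification for multiparametric breast MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-signature segmentation and lesion classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic world does and does not emulate, the numerical choices, and the
design decisions taken where the method description left the design open.
It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The tissue-signature model

A multiparametric breast MRI study is an ordered set of co-registered 3-D
channels: T1w, T2w, a DWI pair at b = 0 and b = 800 s/mm², the derived ADC
map, and N DCE frames. The *tissue signature* of a voxel is its intensity
column across channels in a fixed order — dimensionality D = 5 + N (13 with
the default 8 DCE frames). The modelling assumption is that this vector,
without any spatial context, carries enough contrast to assign one of four
tissue classes (background, fat, glandular, lesion) and, within lesions, to
discriminate benign from malignant phenotypes. The assumption is reasonable
when the channels are co-registered and intensity scales are consistent
across subjects; both are controlled in the synthetic world and must be
approximated by registration and normalization on real data.

The ADC map is derived from the DWI pair by the monoexponential model
`ADC = ln(S0 / Sb) / b`, reported in 10⁻³ mm²/s, clipped to [0, 4] and
masked to 0 where either signal sits below a floor `eps`. In the phantom
the floor is set to three times the additive noise level of the b = 0
channel: this is the standard air-masking step of clinical ADC software,
and without it the ADC map in air is quotient noise, which (realistically)
destroys region growing there.

## 2. Signature harvesting

Regions of interest are grown from seed voxels with a running-mean
acceptance band: a frontier voxel `v` joins the region iff
`|I(v) − μ_R| ≤ max(tol·|μ_R|, eps_abs)` with `tol = 0.05`. The stated "5%
of the signal intensity of the surrounding pixels" is ambiguous between a
relative (coefficient-of-variation) band and a fraction of the global
intensity SD; we implement the relative band as the primary semantics and
use `tol · sd(volume)` as the default absolute floor `eps_abs`, which is
exactly the alternate global-SD reading. The floor matters near zero
intensity (air), where a purely relative band degenerates. Frontier voxels
are evaluated exactly once, in increasing linear-index order, which makes
the grower deterministic; growth is 26-connected in 3-D (a 2-D in-slice
mode is available — the original description does not say which was used).

Per-channel ROIs are fused by logical AND. Fusion uses one representative
image per MRI *sequence* (T1w, T2w, both DWI images, ADC, one early
post-contrast DCE frame), not each DCE frame separately: the frames of a
dynamic series are one sequence, and conjoining 13 noisy masks instead of 6
collapses the ROI to nearly the seed alone. The signature vectors extracted
from the fused ROI still span all D channels.

Balanced sampling pools signatures per class across subjects, caps each
class at 1000 rows, then subsamples all classes to the common minimum, so
the training set is exactly class-balanced. The cap is applied cohort-wide
("across all patients" reading); per-subject capping would be a config-level
variant.

## 3. Eigenimage ground truth

The eigenimage filter is the constrained least-squares contrast filter:
minimize the projection energy of undesired tissue signatures (glandular +
fat) subject to unit response on the desired (lesion) mean signature. Closed
form `w ∝ (ΣuᵢuᵢT + λI)⁻¹ d̄`, rescaled so `wᵀd̄ = 1`; the ridge λ (default
10⁻⁶) handles the rank-deficient case of near-duplicate undesired rows. The
test suite checks the closed form against a brute-force minimizer over the
constraint plane at D ≤ 3.

Thresholding uses the one-sided upper 95% cut, mean + 1.96·SD of the
eigenimage over the foreground ("mean and a 95% confidence interval" of the
histogram). A largest-connected-component postfilter removes threshold
speckle; it can be disabled, and the noiseless-phantom test (Dice 1.0
against truth) passes either way.

## 4. The segmentation network

Five sparse-autoencoder layers of ten nodes, saturating-linear transfer
(`satlin`, clipping to [0, 1]) — hence channels are normalized to [0, 1]
before extraction — with linear decoders, pretrained greedily; each layer's
loss is

    (1/n) Σ‖x − x̂‖² + 0.001·(‖W_enc‖² + ‖W_dec‖²) + 4·KL(ρ̂ ‖ ρ = 0.25)

with the standard KL-divergence sparsity penalty on mean activations
(the description names the hyperparameters but not the penalty formula; the
KL form matches the autoencoder trainers whose parameter names it uses).
A softmax head over the four classes is trained on the stack encodings, and
the whole network is fine-tuned end-to-end on cross-entropy (fine-tuning is
described as optional; it is enabled by default here and reverts
automatically if it does not improve the training loss).

**Optimizer.** The original optimizer is unspecified. Everything is trained
by deterministic full-batch gradient descent with a backtracking line
search: a step that fails to decrease the loss is halved, accepted steps
grow the rate by 10%. This is monotone by construction (the contracts
require final loss ≤ initial loss), reproducible bit-for-bit given the
seed, and robust to the very large KL gradients that arise when a satlin
unit saturates (a plain fixed-rate descent diverges there; that failure is
what motivated the line search). Weight init is uniform
±√(6/(d_in+d_out)); satlin encoder biases start at 0.25 (mid-range) so
units do not start dead; decoder biases start at the column means.

Ties at the voxelwise argmax break toward the lower class id (documented;
the description is silent).

**Normalization across subjects.** Channels are mapped to [0, 1] by robust
percentile min-max (1st/99th). Crucially, when a model is trained on one
set of subjects and applied to others, all subjects must share one set of
per-channel bounds (computed from the training subjects); per-subject
bounds rescale every subject by its own anatomy and destroy between-subject
contrast — empirically this converted occasional total segmentation
failures into clean ones. Whether the original fed raw or normalized
intensities is unstated; the choice is exposed in the config and recorded
in the model.

## 5. Lesion classification

The largest 26-connected component of the predicted lesion class is taken
as the subject's lesion (one lesion per subject — documented policy). A
single sigmoid-encoder / linear-decoder sparse autoencoder (same penalties,
10 nodes) is trained unsupervised on pooled lesion signatures; labels are
never read during encoder training. The statistics layer summarizes each
hidden node over the lesion's voxels by mean, SD (unbiased, 0 for a
one-voxel lesion), max and min, laid out as all means, then SDs, then
maxima, then minima (40 values). The phrase "from each MRI parameter" is
ambiguous since the autoencoder consumes whole multiparametric signatures;
the 40-feature node-statistics layout is the default, and a
`node_plus_channel_stats` mode appends per-channel lesion statistics
(40 + 4D values) as the documented alternate.

The classifier is a linear soft-margin SVM (squared hinge, solved in the
primal by BFGS — deterministic, no QP dependency) with per-class error
costs. The benign:malignant cost ratio is grid-searched over
{1, 1.5, 2, 2.5, 3, 3.5, 4}:1 by cross-validated AUC of the decision
scores; ties prefer the smaller ratio. Malignant is the positive class;
features are standardized with training-fold statistics only.

## 6. The synthetic world

The phantom states the world the method is tested in:

| parameter | default | why |
|---|---|---|
| grid, spacing | 64×64×8 voxels, 1×1×3 mm | axial breast slab at desk scale |
| DCE frames | 8 | enough to express wash-in + wash-out |
| b-values | 0, 800 s/mm² | the stated DWI protocol |
| malignant ADC | 1.26 ± 0.13 ×10⁻³ mm²/s | reported cohort statistic |
| benign ADC | 1.74 ± 0.17 | reported cohort statistic |
| glandular ADC | 2.16 ± 0.40 | reported cohort statistic |
| enhancement | malignant: wash-in to peak 1.2 at frame 3, wash-out to 0.85; benign: monotone rise to 0.7; glandular: mild rise to 0.25 | curve shapes with malignant peak > benign, mirroring the K-trans ordering 0.55 vs 0.25 min⁻¹; kinetics are emulated, not Tofts-fitted |
| noise_sd | 0.02 of each channel's dynamic range | SNR ≈ 50, typical 3-T breast imaging; chosen a priori |
| lesion geometry | ellipsoid, radius 6 voxels in-plane, spacing-corrected in z | no lesion-size distribution is reported; arbitrary default |
| heterogeneity | smooth ±5% intra-lesion field | exercises robustness to non-uniform lesions |

Cohorts jitter geometry per subject and draw each subject's class means
from the class-level SDs above, so the cohort-level ADC distributions match
the reported statistics; lesion enhancement peaks get ×exp(N(0, 0.25))
jitter reflecting the large reported K-trans spread. Noise is additive
Gaussian per channel; Rician noise was rejected for simplicity (at SNR ≈ 50
the difference is negligible away from air, and the ADC floor handles air).

What the phantom does **not** emulate: partial-volume voxels, spatial noise
correlation, bias fields, registration error, multiple or non-ellipsoidal
lesions, and scanner-to-scanner intensity shifts. A green test therefore
establishes correctness of the algorithms and strong performance under the
stated class contrasts — not clinical performance.

Two places where the synthetic world needed interpretation:

* **"Noiseless" end-to-end checks** (Dice exactly 1.0) use
  `noise_sd = 0`, no heterogeneity, and geometry-only cohort jitter
  (`jitter_intensities = FALSE`): with two-subject training folds, drawn
  class means are a sampling-variance effect, not noise, and the exact-1.0
  contract is about the deterministic world.
* **Twofold splits are stratified by phenotype.** At n = 145 random halves
  contain both phenotypes with near-certainty; at desk scale (4–20
  phantoms) an all-benign training fold is likely, and a model that has
  never seen a malignant lesion signature legitimately fails on one.
  Stratifying reproduces the large-cohort property rather than a small-n
  artifact.

## 7. Numerical choices and degenerate inputs

* KL terms clip mean activations to (10⁻⁸, 1−10⁻⁸); the line search
  absorbs the large gradients near the clip.
* `Dice(∅, ∅) = 0` with a warning (the convention is stated nowhere).
* Percent volume difference uses the reference (truth) volume as
  denominator; a symmetric-mean-denominator mode exists.
* AUC is the tie-aware trapezoidal sweep, equal to the normalized
  Mann–Whitney U; verified against exhaustive pair counting.
* Constant channels normalize to all zeros with a warning; zero-variance
  eigenimages and empty ROIs are errors, not silent empties.
* A degenerate one-ratio grid, single-voxel lesions (SD = 0 statistics) and
  lesions missing from a segmentation (record dropped, counted in the
  report) are all handled explicitly.
* Seeded-region-growing and connected components are the only compiled
  (C++) code; everything else is vectorized R.

## 8. Known limitations

* Training is full-batch; cohorts far beyond 10³–10⁴ signatures per class
  would want minibatching (out of scope by design).
* The CNN comparator pools only twice on 5×5 patches (a 2×2 pool on a
  spatial extent below 2 is geometrically impossible; pooling is skipped
  once the extent is < 2 — the source description does not resolve this).
  The CNN trains with deterministic full-batch Adam: the conv loss surface
  makes monotone steepest descent impractically slow, and the comparator's
  contract is "trained supervised, seeded", not monotone descent.
* The eigenimage construction is cited to prior literature without
  equations; the constrained least-squares form here is the standard one
  and is frozen, per-subject by default (cohort-wide fitting would be a
  config variant).
* Registration and pharmacokinetic (Tofts) fitting are out of scope;
  phantoms are generated co-registered and kinetics are emulated by curve
  shape.
* A figure caption mentions an isomap stage in the classification
  framework; the methods text describes SAE + statistics layer + SVM with
  no isomap, and that is what is implemented.
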