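# mpmriseg

Voxelwise tissue-signature segmentation and lesion classification for
multiparametric breast MRI (mpMRI), with a synthetic phantom generator that
makes the whole pipeline testable without patient data.

## The problem

Breast mpMRI acquires several co-registered contrasts — T1-weighted,
T2-weighted, diffusion-weighted imaging (DWI, with a derived apparent
diffusion coefficient map, ADC) and a dynamic contrast-enhanced (DCE)
series. A radiologist reads them jointly: malignant lesions tend to have low
ADC (restricted diffusion) and fast wash-in / wash-out enhancement kinetics,
benign lesions higher ADC and slow persistent enhancement. Fully annotated
training data for this task are expensive; this package implements a
pipeline that needs only sparse seed points per tissue class.

It is aimed at quantitative-imaging researchers who want a reference
implementation of the tissue-signature approach, a reproducible synthetic
benchmark for it, or building blocks (region growing, eigenimage filtering,
sparse autoencoders, cost-weighted SVM, evaluation metrics) for their own
experiments.

## The model

The **tissue signature** of voxel *v* is the vector of its intensities
across all channels,

    TS(v) = [ T1w(v), T2w(v), DWI_b0(v), DWI_b800(v), ADC(v), DCE_1(v), ..., DCE_N(v) ]ᵀ ∈ ℝᴰ.

The pipeline has four stages:

1. **Signature harvesting.** From a few seed voxels per class
   (background / fat / glandular / lesion), a seeded region grower with a 5%
   running-mean tolerance band produces an ROI on each MRI sequence image;
   the per-sequence ROIs are fused by logical AND. Signatures are pooled
   across subjects and sampled class-balanced (≤ 1000 per class).
2. **Eigenimage ground truth.** A linear filter `w` minimizing
   `Σᵢ (wᵀuᵢ)² + λ‖w‖²` subject to `wᵀd̄ = 1` (undesired signatures `uᵢ`:
   glandular + fat; desired mean `d̄`: lesion) projects the study onto a
   lesion-contrast volume; thresholding at mean + 1.96·SD of the eigenimage
   histogram gives the radiological ground-truth lesion mask.
3. **Segmentation.** A stacked sparse autoencoder (SSAE; 5 layers × 10
   saturating-linear nodes, L2 penalty 0.001, KL sparsity penalty with
   target activation ρ = 0.25 and weight β = 4) is pretrained greedily on
   signatures, topped with a softmax head over the four classes, fine-tuned,
   and applied voxelwise. Evaluated by twofold cross-validation with the
   Dice similarity `DS = 2|A∩B| / (|A|+|B|)`.
4. **Lesion classification.** Lesion-voxel signatures are encoded by an
   unsupervised sigmoid sparse autoencoder; a statistics layer summarizes
   each hidden node by (mean, SD, max, min) over the lesion, giving a
   40-dimensional feature vector per lesion; a linear SVM with
   benign:malignant misclassification-cost ratios grid-searched over
   {1, 1.5, 2, 2.5, 3, 3.5, 4} : 1 (selected by leave-one-out
   cross-validated AUC) labels lesions benign or malignant.

The **phantom generator** emulates this world with known truth: four-class
breast anatomy on a 64×64×8 grid (1×1×3 mm), class-conditional ADC values
(malignant 1.26 ± 0.13, benign 1.74 ± 0.17, glandular 2.16 ± 0.40,
×10⁻³ mm²/s), DWI synthesized via `S_b = S₀·exp(−b·ADC)`, and malignant
wash-out vs benign persistent DCE curves.

## Worked example

```r
library(mpmriseg)

cohort <- generate_cohort(10, benign_fraction = 0.5, phantom_spec(), seed = 11)

# shared intensity scale + signature harvesting on the first 8 subjects
bounds <- compute_channel_bounds(lapply(cohort[1:8], `[[`, "study"))
norm   <- lapply(cohort, function(p) normalize_channels(p$study, bounds = bounds))
harv   <- lapply(1:8, function(i)
  harvest_signatures(norm[[i]], auto_seeds(cohort[[i]]$truth, 3, seed = i)))
train_set <- sample_balanced(harv, cap_per_class = 1000, seed = 2)
model <- train_ssae(train_set, ssae_config(seed = 3),
                    channel_order = norm[[1]]$channel_order)

for (i in 9:10) {
  seg <- segment_study(model, norm[[i]])
  cat(sprintf("%s (%s): lesion Dice %.3f, lesion volume %.0f mm^3 (truth %.0f)\n",
      cohort[[i]]$study$subject_id, cohort[[i]]$lesion_phenotype,
      dice(seg$labels == 3, cohort[[i]]$truth$labels == 3),
      lesion_volume(seg$labels == 3, cohort[[i]]$study$voxel_spacing),
      cohort[[i]]$lesion_volume_mm3))
}
```

prints (exactly, given these seeds):

```
training signatures: 2376 rows, 13 channels
sub009 (malignant): lesion Dice 1.000, lesion volume 798 mm^3 (truth 798)
sub010 (malignant): lesion Dice 0.999, lesion volume 1416 mm^3 (truth 1413)
```

i.e. the held-out phantoms are segmented with near-perfect lesion overlap
and their volumes recovered to within a few mm³. The full end-to-end run
(cohort simulation → signatures → eigenimage truth → twofold segmentation →
SAE-SVM classification → report) is driven by

```r
run_pipeline(pipeline_config(), outdir = "mpdl_run", seed = 1)
```

or from the shell via `inst/cli/mpmriseg run-all --outdir mpdl_run --seed 1`;
`mpdl_run/summary.json` then holds per-subject Dice, cohort AUC /
sensitivity / specificity, volume agreement (percent difference,
correlation, Bland–Altman limits) and every seed and switch used.

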