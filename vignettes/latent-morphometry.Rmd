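---
title: "Simulating disease progression in latent space: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating disease progression in latent space: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`latentmorph` implements a latent-space approach to studying structural
disease patterns — here, multiple-sclerosis-like brain atrophy — in 2D MR
slices:

1. a **style-based generative model** is trained unsupervised on slice
   images of two cohorts (healthy-control-like and MS-like);
2. individual images are **projected** (GAN inversion) into the model's
   extended latent space W+, giving each subject a latent code that
   reconstructs its image;
3. a **linear SVM** separating the two cohorts' codes yields a unit normal
   vector — the *disease direction* — and moving a subject's code along it
   synthesizes a plausible progression (or regression) of the disease
   pattern;
4. **morphometry** quantifies the simulated progression through the brain
   parenchymal fraction, BPF = (V~GM~ + V~WM~) / (V~GM~ + V~WM~ + V~CSF~),
   computed from a k-means tissue segmentation of each edited slice.

Because clinical MR images cannot be shipped, the package includes a
first-class synthetic-data module (`make_phantom()`, `sample_cohort()`)
whose phantoms carry exact tissue masks. The phantoms serve two roles: they
are the training/evaluation data for the end-to-end pipeline, and their
masks are ground-truth oracles for the segmentation and BPF code.

# The phantom model

A phantom is a schematic axial brain slice on a `size`×`size` raster
(power of two, default 64; the GAN pipeline uses 32):

* **head**: an ellipse whose semi-axes scale weakly with `age_proxy`
  (+0.15 %/year around age 38) and shrink with `slice_position`
  (3 %/index), emulating head-size and slice covariates;
* **cortex (GM)**: a ribbon at the head boundary with relative thickness
  `0.16 * (1 - 0.6 * cortical_thinning)`;
* **ventricles (CSF)**: two vertical ellipses near the center whose area
  scales linearly with `ventricle_scale`;
* **WM**: the remaining interior; **lesions**: small discs placed on a ring
  around the ventricles, clipped to parenchyma;
* **intensities**: for the multi-echo contrast, tissue τ in channel c has
  mean S₀(τ)·exp(−TE~c~/T2\*(τ)) with TE = 8.12, 13.19, 19.26 ms and
  (S₀, T2\*) = WM (0.85, 55 ms), GM (0.65, 70 ms), CSF (0.34, 200 ms), so
  every channel keeps the T1w ordering WM > GM > CSF while decaying at
  tissue-specific rates. The ADC contrast uses one map (CSF ≈ lesion 0.9 >
  GM 0.55 > WM 0.40) duplicated to three identical channels, matching how
  single-channel inputs are fed to a 3-channel generator.
* **noise**: additive Gaussian, SD 0.02 by default — small enough that
  k-means segmentation stays essentially exact (the tests require ≥ 98 %
  pixel agreement), nonzero so the pipeline is exercised under noise.

Cohort-conditional attribute distributions (all config-exposed via
`cohort_defaults()`): `ventricle_scale` ~ LogNormal(0, 0.18) for HC with
the MS log-mean shifted +0.25; `lesion_count` ~ Poisson(0.3 HC / 4 MS);
`cortical_thinning` ~ Beta(2, 8) HC / Beta(4, 6) MS; `age_proxy` Gaussian
with cohort means 36.94/38.75 and SDs 12.55/10.08. Effect sizes are free
parameters of the simulation — chosen once so that the two cohorts overlap
substantially (single-attribute classification is far from perfect) while
the cohort mean BPF difference is clearly measurable.

What the phantoms deliberately do **not** model: gyral/sulcal texture,
bias fields, registration error, partial-volume effects, or any 3D
structure. Consequently, a passing end-to-end run shows that the *method*
(training → inversion → SVM direction → BPF trend) is implemented
correctly and recovers a planted cohort difference; it does not show that
the method works on clinical data.

# The generative model

The generator follows the style-based design: a 4-layer fully connected
mapping network `Z → W` (latent dimension d = 64 in the toy configuration)
and a synthesis network that starts from a learned 4×4 constant and doubles
resolution per block, with one style input per convolution
(L = 2·log₂(res) − 2 style slots) and an additive per-layer noise map with
a learned gain (initialized at 0). Convolutions are style-modulated with
weight demodulation; equalized learning rate is used everywhere; the
mapping network runs at a 0.01 learning-rate multiplier. The discriminator
mirrors the generator with residual down-sampling blocks and a minibatch
standard-deviation channel.

Training uses the non-saturating logistic loss, R1 regularization applied
lazily every 16 discriminator steps (γ = 1 by default), Adam with
(β₁, β₂, ε) = (0, 0.99, 1e−8) and learning rate 0.0025 for both networks,
and adaptive discriminator augmentation (ADA) whose only augmentation is
horizontal mirroring: the mirroring probability p rises by a fixed step
when the overfitting statistic r~t~ = E[sign D(x~real~)] exceeds its
target (0.6) and falls otherwise, clamped to [0, 1].

Because no automatic-differentiation framework is available in this
R environment, all backward passes are hand-written and verified against
central finite differences in the test suite (`test-nn-grad.R`). The R1
term needs second derivatives of the discriminator; its parameter gradient
is computed as a central-difference Hessian-vector product
(∇~θ~‖∇~x~D‖² = 2∇~θ~⟨v, ∇~x~D⟩ with v = ∇~x~D held fixed, differenced
along ±εv), which is exact almost everywhere for the piecewise-linear
discriminator and costs two ordinary backward passes.

Generation quality is tracked with the Fréchet distance between Gaussian
fits of feature embeddings. The embedder is pluggable; the default is a
fixed-seed random two-stage convolutional feature map, which requires no
downloaded weights and is reproducible everywhere. Numbers from different
embedders are on different scales and are never compared — the package
only uses the metric *relatively* (start vs. end of a training run).

# Projection

`project_image()` inverts a target image through a trained generator by
jointly optimizing the extended latent code w⁺ (one d-vector per style
layer) and every noise-injection map with Adam (β = (0, 0.99)):

* **Initialization**: N = 10,000 latent samples are drawn in Z, mapped to
  W, and synthesized with zero noise; the initial w is the mean of the 100
  samples whose images score highest in SSIM against the target (both N
  and the top-k are configurable; top-k = 1 selects the single best,
  top-k = N recovers plain W-mean initialization). The scalar spread σ~w~
  (root mean per-component variance of all sampled w) scales the
  stabilizing noise.
* **Schedules**: learning rate ramps 0 → 0.1 over the first 50 iterations
  and back to 0 over the last 250, both cosine; Gaussian noise with SD
  0.05·σ~w~·t² is added to w⁺ each step, with t falling linearly from 1 to
  0 over the first 750 iterations.
* **Loss**: a perceptual distance (sum over feature maps of mean squared
  feature differences; the embedder is pluggable and defaults to fixed-seed
  random multi-scale convolution features) plus c = 10⁵ times the noise
  regularizer.
* **Noise regularizer**: for each map, a pyramid is built by 2× average
  pooling with ×2 amplitude compensation (so unit-variance noise stays
  unit variance) down to 8×8, and each level contributes the squared
  resolution-normalized lag-1 autocorrelations under circular shifts.
  Circular shifts keep the summand count constant per map. Maps smaller
  than 8×8 (the 4×4 input-block map) are optimized but not regularized.
  After every iteration each map is renormalized to zero mean and unit
  variance (per layer, not per pyramid level).

Design choices worth flagging: σ~w~ is a scalar, not per-component; the
noise-SD expression is read as 0.05·σ~w~·t²; Adam β values for projection
reuse the training values. All are config-exposed.

The key correctness property — checked in the acceptance tests — is
*parameter recovery*: projecting an image that the generator itself
produced must drive the perceptual distance below 10 % of its initial
value within 300 iterations and the relative image MSE below 1e−2 over a
1000-iteration run, on a 32×32, d = 64 toy generator. Noise gains are
initialized at zero, so for an untrained generator the target is exactly
attainable. Recovery at this tolerance needs the single-best SSIM
initialization (`init_top_k = 1` over 2000 samples) and Adam momentum
(β = (0.9, 0.999)): W+ inversion under a random-feature perceptual loss
has attraction basins, and the top-k *mean* initialization can average
across them, stranding the optimizer near a wrong basin at any iteration
budget. Both knobs are ordinary configuration points; the defaults keep
the reference behavior.

# Semantic directions and conditional manipulation

`fit_direction()` trains a linear SVM (C = 1, no feature standardization —
the hyperplane lives in raw latent coordinates; both config-exposed) on
flattened W+ codes (length L·d, so the direction can differ per style
layer) and returns the unit hyperplane normal oriented from cohort A
toward cohort B, with a 10-fold cross-validation report (per-fold hold-out
accuracy and pairwise cosines between fold directions). The released
direction is always the full-data fit.

`conditionalize(n1, n2)` removes the n2 component,
n₁ − (n₁ᵀn₂)n₂, and — a documented divergence from the plain formula —
renormalizes to unit length so α keeps a consistent scale across
conditionalized and raw directions.

`manipulate_latent()` synthesizes G~syn~(w⁺ + α·n) over an α grid using the
projection's fixed noise maps, so α = 0 reproduces the reconstruction
bit-for-bit. Editing is additive: α then β equals α+β exactly.

# Morphometry

`segment_tissues()` clusters pixel intensities with k-means (k = 4,
seeded k-means++ initialization, 10 restarts, run per image). Cluster →
tissue assignment is rule-based: the cluster that dominates the image
border is background (this one rule covers both contrasts, rather than
assuming background is darkest); the remaining three clusters are sorted
by centroid intensity and mapped CSF < GM < WM for T1w and
WM < GM < CSF for ADC. Segmentation uses channel 1 only. BPF comes from
pixel counts on the single slice. `paired_ttest()` is a standard paired
Student t-test that returns an explicit `zero_variance` flag instead of an
infinite statistic when all differences vanish.

# The end-to-end experiment

`run_pipeline()` chains the stages with cached, hash-keyed artifacts. The
default configuration is the package's scaled-down study condition,
chosen to exercise the full method on one CPU in tens of minutes:

* 1000 + 1000 phantoms at 32×32, multi-echo contrast, noise SD 0.02;
* toy GAN: d = 64, channel widths 48/48/24/12 (4×4 → 32×32), batch 16,
  10k images shown (625 steps), ADA mirroring on;
* 20 + 20 subjects projected with 150 iterations, N = 256 init samples,
  top-25 SSIM initialization (schedule lengths scaled proportionally);
* MS direction from the 10-fold SVM on the 40 flattened codes;
* HC subjects edited toward MS over six α values in [0, α~max~], MS
  subjects toward HC over [−α~max~, 0]. α is in latent-distance units,
  and its useful range depends on the latent geometry of a given training
  run, so α~max~ defaults to 6× the median absolute hyperplane distance
  of the projected cohort (`edit$alpha_scale`); a fixed α~max~ can be set
  instead.

With these conditions the pipeline reproduces the qualitative signature of
simulated disease progression: mean segmented BPF at α~max~ falls below
its α = 0 baseline as HC subjects are pushed toward MS, the large majority
of subjects show a negative BPF-vs-α rank correlation, and the
training-run Fréchet feature distance ends far below its untrained
starting value. These are exactly the quantities the acceptance tests
assert and `scripts/acceptance.R` recomputes; the vignette makes no
claims beyond them. Absolute BPF levels at this scale sit below the
phantoms' true values because the toy GAN's reconstructions are imperfect;
the per-α means are noisy and need not decrease monotonically — the
endpoint contrast and the per-subject trend are the robust readouts.

At this scale the latent cohorts overlap heavily (fold-wise SVM hold-out
accuracy is modest), which mirrors the fact that a 40-subject sample in a
512-dimensional latent space identifies the cohort axis only coarsely;
the BPF trend is nevertheless recovered because the manipulation response
is averaged over subjects and α levels.

# Numerical and degenerate-input policy

* Tissue masks are exact partitions by construction; `analytic_bpf()`
  rejects an empty intracranial region.
* `segment_tissues()` rejects constant images and images with fewer than
  4 distinct intensities.
* `frechet_distance()` validates symmetry and positive semidefiniteness
  (tolerance 1e−6 relative) and clamps tiny negative results of the trace
  formula to zero.
* `conditionalize()` rejects near-parallel pairs (residual norm < 1e−8).
* Projection aborts with the iteration index if the loss becomes
  non-finite; noise maps are renormalized with population variance.
* All stochastic entry points take explicit seeds, restore the caller's
  RNG state, and derive per-subject seeds below 2³¹.

# Known limitations

* The phantom geometry is schematic; none of the texture-level cues real
  MS reading relies on are present, and lesion effects on T1w contrast are
  minimal by design.
* Toy-scale training (32×32, ~10k images shown) leaves visible
  reconstruction error in the brain periphery; projection quality, not the
  SVM, is usually the binding constraint on direction quality.
* BPF here is a single-slice pixel ratio, not a volumetric measure.
* The Fréchet and perceptual metrics use random-feature embedders;
  absolute values are not comparable to published numbers obtained with
  pretrained backbones, and the package never makes such comparisons.
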