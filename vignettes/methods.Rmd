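---
title: "Radiomics-guided dual-channel fusion for parkinsonian FDG-PET: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomics-guided dual-channel fusion for parkinsonian FDG-PET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Idiopathic Parkinson's disease (IPD), multiple system atrophy (MSA) and
progressive supranuclear palsy (PSP) overlap clinically but show distinct
regional glucose-metabolism patterns on ^18^F-FDG PET: MSA is associated
with reduced uptake in the putamen, pons and cerebellar (dentate) region,
PSP with reductions in the caudate nucleus, thalamus and midbrain, and IPD
with relative putaminal preservation and mild posterior cortical
reduction. `petfusion` implements a three-class classifier that fuses
three complementary views of a PET volume:

1. **Radiomics**: 107 quantitative features (18 first-order, 14 shape, 24
   GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM, 14 GLDM) per region over a 20-region
   parcellation — 2,140 candidate features per subject, computed on
   SUVR-normalized volumes.
2. **A local channel**: a three-layer dilated 3D convolutional encoder
   (3×3×3 kernels, dilation rates 1/2/3, "same" padding so spatial
   resolution is maintained; effective receptive field 13 voxels), global
   average pooling to a latent vector, and a softmax head. Interpreted
   post hoc by Layer-CAM.
3. **A global channel**: cubic patch embedding (6×6×6 kernel, configurable
   stride; overlapping when stride < kernel) into a pre-layer-norm
   Transformer encoder whose prepended context token is the global average
   of the patch embeddings. Interpreted by attention rollout.

A three-stage cross-cohort cascade selects stable radiomics features, the
top latent dimensions of each channel are appended, and a gradient-boosted
tree ensemble (`multi:softmax` objective in its soft-probability form,
learning rate 0.025, gamma 0.1, maximum depth 6, L2 lambda 2) performs the
final classification. Shapley attributions, their cross-cohort
concordance, and group-average attribution maps provide the
interpretability layer.

## The phantom generator: what it emulates and what it does not

Clinical cohorts for this problem are private, so the package ships a
phantom module that makes every stage testable. A subject is generated as

    voxel = regional baseline × disease factor × (1 + ε),  ε ~ N(0, sd)

on a 20-region ellipsoidal parcellation inside a brain envelope, followed
by Gaussian smoothing (FWHM 10 mm, the standard PET preprocessing width).
Defaults, chosen once as the study conditions:

* effect factors — MSA: putamen 0.85, pons 0.85, dentate nucleus 0.88;
  PSP: caudate 0.85, thalamus 0.88, midbrain 0.85; IPD: occipital cortex
  0.92, putamen 1.05; healthy controls all 1.0;
* voxel noise sd 0.10 (multiplicative, before smoothing);
* baselines mimicking FDG gray-matter contrast (striatum 1.25, cortex 1.0,
  brainstem 1.05, background tissue 0.75);
* a second, "external" generator with global gain ×1.1, noise sd 0.12 and
  effect magnitudes shrunk 10% toward 1, to exercise the cross-cohort
  machinery.

The phantom emulates regional multiplicative hypometabolism, subject
noise, smoothing-induced texture, and between-center nuisance shifts. It
does **not** emulate anatomically realistic geometry, scanner physics,
partial-volume effects, or within-class biological heterogeneity; passing
tests demonstrate that the pipeline recovers planted regional effects
under these idealized conditions, not clinical performance.

## Preprocessing conventions

* Smoothing is separable Gaussian with σ = FWHM / (2√(2 ln 2)) per axis in
  voxel units, mirror reflection at boundaries (interior-supported signals
  keep their total intensity to < 0.1%).
* SUVR reference = whole-brain (envelope) mask mean, so the masked mean of
  a SUVR volume is exactly 1; idempotent.
* Image z-scoring (network inputs) uses the mask mean and **population**
  sd; voxels outside the mask are set to 0; idempotent. Radiomics is
  computed on SUVR volumes (so the bin width has a stable meaning), the
  channels receive z-scored SUVR volumes.

## Radiomics conventions

Discretization is fixed-bin-width (default 0.05 on the SUVR scale),
anchored at the ROI minimum: `level = floor((x − min)/w) + 1`, so a range
that is an exact multiple of the bin width opens its own top level.
Texture matrices use the 13 unique 3D directions at distance 1; the GLCM
is symmetrized and **summed over directions** before normalization, and
the run/zone/dependence matrices are likewise direction-summed. GLSZM
zones are 26-connected components; NGTDM uses 26-neighbourhood means
(voxels without an in-ROI neighbour do not contribute); GLDM dependence is
1 + the number of 26-neighbours within level tolerance 0 (the centre
counts, so dependence ≥ 1). Shape features use the voxelized surface
(exposed faces) and voxel-count volume rather than a triangulated mesh,
and principal-axis lengths come from the eigenvalues of the voxel-centre
covariance; this overestimates surface area relative to a mesh but is
fully deterministic and convention-stable. Degenerate ROIs take finite
analytic limits (constant ROI: zero variance/contrast features, entropy 0;
single voxel: unit dependence, NGTDM coarseness capped at 10^6). Every
texture kernel is pinned by brute-force enumeration oracles in the test
suite.

The bank text names GLCM/GLRLM/GLSZM/NGTDM plus shape and first-order
families; the count of 107 is only reachable when the 14 GLDM features are
included, so GLDM is part of the default bank.

## Network training choices

Both channels train with cross-entropy, Adam, mini-batches, seeded
shuffling and initialization, and optional early stopping on a validation
fraction, plus global-norm gradient clipping (default 5). Two choices
deserve explanation:

* **Latent standardization (local channel).** Global average pooling over
  tens of thousands of voxels concentrates the latent distribution within
  ~10^-3 of its mean, orders of magnitude below the between-subject class
  signal's scale relative to the offsets, so a raw softmax head cannot use
  it within a small step budget. The head therefore sees the z-scored
  latent; the statistics are re-estimated over the training set at the
  start of each epoch (constants within an epoch and in the backward
  pass) and frozen afterwards, keeping evaluation deterministic.
* **Per-group learning rates.** The head trains at the configured rate
  while the convolutional body drifts slower (default ×0.05), so the
  frozen-per-epoch latent statistics stay representative; this removed a
  seed-dependent divergence mode observed with a single shared rate.

Desk-scale presets (the defaults of `default_config()`) operate on
volumes resized to 16×18×16 (local) and 24×24×24 (global, 64 patch tokens
at stride 6) with 4/8/12 filters and embed dimension 32, so the full
pipeline runs on one CPU; the clinical-scale geometry (79×95×69 input,
32/64/128 filters; 78×96×66, overlapping stride-3 patches) remains the
default of the channel constructors themselves. The problem sizes used by
the test suite (two cohorts of 60 training + 30 test subjects per class on
a 32×36×32, 4 mm grid) are the package's desk-scale study conditions.

## Selection cascade

Stage 1 removes columns with variance < 10^-8 in either cohort or with a
two-sample Kolmogorov–Smirnov p-value below 0.01 between cohorts. Stage 2
screens with elastic net (α = 0.5) using one-vs-rest responses, a 100-point
λ grid log-spaced over 4 decades from λ_max, 10-fold CV and the
minimum-MSE λ, then refits LASSO (α = 1) per cohort and keeps features
present in both supports whose per-class weight profiles correlate across
cohorts above r = 0.6 (the weight-profile reading of inter-cohort
correlation; the alternative — correlating feature values across matched
subjects — is not meaningful for phantom cohorts with distinct subjects,
and the chosen reading is isolated in `cross_cohort_refine()`). Stage 3
prunes greedily by |weight|, keeping a feature only if its |Pearson r|
with every kept feature is ≤ 0.5. Latent dimensions are ranked by the same
elastic-net machinery (aggregate |weight| across the three one-vs-rest
problems) and the top 5 per channel are kept — the fused specification is
radiomics, then local, then global latents. With a single cohort the
cross-cohort rules are skipped and logged. The coordinate-descent solver
is warm-started active-set descent; its orthonormal-design closed form and
agreement with an independent implementation are pinned by tests.

## Interpretability

Shapley values use the interventional value function (background rows with
coalition features replaced by the instance's values), exact enumeration
up to 20 features and a seeded permutation estimator with Monte-Carlo
standard errors and exact additivity enforcement for routine use; the
background is a seeded subsample of training rows (default cap 50).
Cross-cohort reproducibility is summarized as the Pearson correlation of
per-class mean-|φ| profiles between the blind-test and external cohorts.
Layer-CAM is `ReLU(Σ_k ReLU(∂y_c/∂A_k) ⊙ A_k)` at a chosen conv layer
(already in input geometry because the encoder maintains resolution),
min-max normalized; rollout multiplies head-averaged, residual-adjusted,
row-renormalized attention matrices across layers and paints the context
row over patch footprints. Note that with uniform attention the
residual-adjusted rollout of two layers is (3U + I)/4, not uniform — the
definition keeps a diagonal component by construction.

## Known limitations

* **Attribution maps do not reliably localize planted effects at desk
  scale.** After per-image z-scoring, the planted hypometabolic levels
  fall into the same intensity band as normal cortex, and both channels
  learn translation-invariant band-occupancy features; their saliency mass
  sits on large cortical shells rather than the small planted nuclei, and
  the planted-vs-unaffected region contrast of group maps fluctuates
  around or below 1 across seeds and training lengths. The corresponding
  acceptance check is implemented faithfully and is expected to fail
  under the frozen study conditions; at clinical scale with real texture
  differences the same code paths may behave differently, but nothing at
  desk scale demonstrates that.
* The two-cohort phantom shares one atlas and differs only in gain, noise
  and effect magnitude; real between-center variation is richer.
* Elastic-net CV at desk scale uses a convergence tolerance of 2×10^-5;
  the closed-form tests use much tighter tolerances on small problems.
* The boosted classifier's probability rows sum to 1 within single
  precision (~10^-7).
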