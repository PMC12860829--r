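# petfusion

Differential classification of parkinsonian syndromes — idiopathic
Parkinson's disease (IPD), multiple system atrophy (MSA) and progressive
supranuclear palsy (PSP) — from 3D ^18^F-FDG PET brain volumes, for
researchers building interpretable imaging classifiers and for method
developers who need a fully reproducible, self-contained testbed.

The package fuses three views of a PET volume:

* **Radiomics**: 107 IBSI-style features per region (first-order, shape,
  GLCM, GLRLM, GLSZM, NGTDM, GLDM) over a 20-region parcellation — 2,140
  candidates per subject on SUVR-normalized volumes,
* a **local channel** — a dilated 3D convolutional encoder (3×3×3
  kernels, dilations 1/2/3, "same" padding, global average pooling),
* a **global channel** — a 3D patch-embedding Transformer with a pooled
  context token,

then reduces the radiomics candidates with a three-stage cross-cohort
cascade (variance/Kolmogorov–Smirnov stability filter; elastic-net screen
at α = 0.5 with 10-fold CV and the minimum-MSE λ followed by per-cohort
LASSO refits keeping features with inter-cohort weight-profile correlation
r > 0.6; greedy redundancy pruning at |r| > 0.5), appends the top-5 latent
dimensions per channel, and classifies with gradient-boosted trees
(softmax objective, learning rate 0.025, γ = 0.1, depth 6, λ = 2).
Interpretability comes from exact/sampled Shapley attributions with
cross-cohort concordance, Layer-CAM saliency maps
`ReLU(Σ_k ReLU(∂y_c/∂A_k) ⊙ A_k)`, and attention-rollout maps
`R = Â_L ⋯ Â_1` with `Â = rownorm(A + I)`.

Because clinical cohorts for this task are private, a phantom module
generates parcellated PET cohorts with disease-specific multiplicative
regional hypometabolism (MSA: putamen/pons/dentate; PSP:
caudate/thalamus/midbrain; IPD: mild occipital reduction), voxel noise and
10 mm FWHM smoothing, plus a second "external" generator with shifted
nuisance parameters — so every stage is testable end to end. See the
methods vignette (`vignettes/methods.Rmd`) for all conventions and
limitations.

## Worked example

```r
library(petfusion)

# the full desk-scale pipeline: two phantom cohorts (60 train + 30 test
# subjects per class each), radiomics + dual-channel latents, selection,
# fusion classification, SHAP concordance, attribution maps
report <- run_pipeline(list(seed = 42))
print(report)
#> <pf_report> seed 42: 2140 candidates -> 21 fused features
#>   blind-test: acc 0.989, macro AUC 1.000
#>   external:   acc 0.956, macro AUC 0.999
#>   SHAP concordance r: IPD 1.00, MSA 1.00, PSP 1.00

head(report$selection$radiomics, 3)
#> [1] "occipital_cortex_firstorder_Mean"
#> [2] "pons_firstorder_Median"
#> [3] "midbrain_glrlm_RunLengthNonUniformityNormalized"
```

Reading the output: of the 2,140 radiomics candidates the cascade retains
a handful of stable, nonredundant features (here led by occipital mean
uptake and pontine/midbrain texture — the planted IPD and MSA/PSP effect
regions), which are fused with 5 local + 5 global latent features. The
fused classifier separates the three syndromes nearly perfectly on the
held-out phantom split (accuracy 0.989, macro one-vs-rest AUC 1.0),
transfers to the shifted external cohort (0.956 / 0.999), and the per-class
mean-|SHAP| importance profiles of the two cohorts correlate at r ≈ 1,
i.e. the model relies on the same biomarkers in both populations.

Individual stages are exported too — e.g.
`build_parcellation()`, `simulate_cohort()`, `gaussian_smooth()`,
`to_suvr()`, `zscore_image()`, `compute_features()`, `extract_table()`,
`select_features()`, `train_classifier()`, `shapley_exact()`,
`layer_cam()`, `rollout_map()`. A thin command-line wrapper lives at
`inst/cli/petfusion.R` (verbs `simulate`, `extract`, `run-all`).

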