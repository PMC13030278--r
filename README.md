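# strokemark

Quantitative imaging biomarkers for ischemic stroke, downstream of
deep-learning segmentation.

Modern stroke pipelines segment the infarct (and the corticospinal tracts,
CST) with neural networks, but the *numbers* clinicians and researchers
reason about come afterwards: how big is the lesion, what shape is it,
where does it sit, how heterogeneous is its tissue, and how much of the
motor pathway does it hit? `strokemark` implements that downstream stage
for R users working with NIfTI data: it fuses candidate lesion masks from
several segmentation models, extracts a fixed registry of 19 named
biomarkers per subject from the ADC map and the masks, and runs an
exploratory protocol that models the dichotomised modified Rankin Scale
outcome (favourable mRS ≤ 2 vs unfavourable mRS > 2) from those
biomarkers. A seeded synthetic phantom generator makes every stage testable
without clinical data.

## What it computes

**Fusion** — voxel-wise majority voting over candidate masks: lesion iff a
strict majority of models agree (2 of 3 in the reference setting).

**Morphology** — volume `V = Σ L(x,y,z) · v_voxel / 1000` (mL); surface
area `A` from an anti-aliased isosurface mesh; sphericity
`π^(1/3)·(6V)^(2/3)/A`; solidity `V / V_hull`; elongation
`√(λ₃/λ₁)` of the voxel-cloud covariance; compactness `A³/(36π·V²)`.

**Spatial & intensity** — intensity-weighted centroid
`Σ x·I(x,y,z) / Σ I(x,y,z)` (per axis, voxel and world mm); max and mean
in-lesion ADC; quadrant distribution about the two index midplanes
(LA/LP/RA/RP).

**Texture** — slice-wise grey-level co-occurrence matrices (256 levels,
d = 1,2,3, directions 0°/45°/90°/135°, symmetric, probability-normalised,
both pixels in-mask) yielding contrast, dissimilarity, homogeneity, ASM,
energy and correlation, averaged over directions, distances and slices,
plus Shannon entropy of the slice histograms: seven texture features per
subject.

**Tract overlap** — per hemisphere, `Overlap% = 100 · V(lesion ∩ CST) /
V(CST)`, with tract masks resampled onto the lesion grid by nearest
neighbour.

**Outcome modelling** — training-only ANOVA selection of the top 17 of 19
features, stratified 80/20 split, grid-search 5-fold CV of tree ensembles
(random forest by default, xgboost optional), held-out metrics (accuracy,
precision, recall, F1, ROC-AUC, MCC) with 95% bootstrap percentile CIs, and
impurity plus permutation feature importance.

See the methods vignette (`vignettes/strokemark-methods.Rmd`) for the
conventions, numerical choices and limitations.

## Worked example

Everything below runs on synthetic data; no downloads.

```r
library(strokemark)

spec <- phantomSpec()            # strong-signal study conditions
s <- makeSubject(spec, 42)       # ADC + 3 noisy candidate masks + tracts
rec <- extractSubject("subj-042", s$adc, s$candidates,
                      s$cstLeft, s$cstRight)
round(t(rec[-1])[c(1:8, 16, 22, 25:26), ], 3)
#> volume_ml                8.584
#> surface_area_mm2      1940.257
#> sphericity               1.045
#> solidity                 0.737
#> elongation               0.568
#> compactness              0.876
#> max_intensity         1314.054
#> avg_intensity          657.095
#> contrast              2139.042
#> entropy                  4.767
#> cst_left_overlap_pct     0.000
#> cst_right_overlap_pct   40.455
```

This subject's lesion is an 8.6 mL, moderately elongated ellipsoid with the
ADC-dark core the phantom builds in (mean in-lesion ADC 657 vs background
1100 ×10⁻⁶ mm²/s), touching none of the left but 40% of the right
tract-shaped mask.

A full cohort and the outcome protocol:

```r
ph  <- phantomCohort(spec, 120, seed = 7)    # generate + extract 120 subjects
res <- runOutcomeModel(ph$table, modelConfig(seed = 7, bootstrapReps = 500))
round(res$report$metrics, 3)
#> accuracy precision    recall        f1   roc_auc       mcc
#>    0.875     0.867     0.929     0.897     0.921     0.742
res$report$ci[5, ]                           # ROC-AUC with bootstrap CI
#>    metric     point       low high skipped
#> 5 roc_auc 0.9214286 0.7885417    1       0
head(res$importance$ranking, 2)
#> [1] "cst_left_overlap_pct"  "cst_right_overlap_pct"
```

On this strong-signal phantom (outcomes driven by lesion–tract overlap),
the held-out AUC is 0.92 and the two overlap columns rank first in
permutation importance — the pipeline recovers the planted association.

A thin CLI over the same functions ships in
`inst/scripts/strokemark.R` with subcommands `fuse`, `extract`, `overlap`,
`cohort`, `simulate` and `train-eval`.

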