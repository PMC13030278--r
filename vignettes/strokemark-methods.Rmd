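---
title: "Methods: lesion biomarkers, texture, tract overlap and outcome modelling"
author: "strokemark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion biomarkers, texture, tract overlap and outcome modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokemark)
```

# Overview

`strokemark` implements the quantitative stage of an automated stroke-MRI
biomarker pipeline. Its inputs are the artifacts that upstream deep-learning
tools produce for each subject: an ADC (apparent diffusion coefficient) map,
one or more binary lesion masks from segmentation models, and binary
left/right corticospinal-tract (CST) masks. From these it computes a fixed
registry of 19 named imaging biomarkers per subject, assembles cohorts, and
runs an exploratory protocol that models the dichotomised modified Rankin
Scale (mRS) outcome — favourable (mRS ≤ 2) versus unfavourable (mRS > 2) —
from the imaging features. Segmentation itself, tractography and any image
registration are out of scope; inputs are assumed skull-stripped and
co-registered.

All stages operate on three S4 classes — `VoxelGrid` (shape, spacing and the
voxel-to-world affine), `ScalarVolume` and `BinaryMask` — with explicit grid
checks (`assertSameGrid()`, tolerance 1e-4 mm) instead of silent
broadcasting. Volumes are reoriented to the closest-to-RAS axis convention at
load time so that axis-based definitions (quadrants, axial slicing) mean the
same thing for every input. Reported voxel coordinates are 0-based, matching
the NIfTI convention in which the header affine maps 0-based indices to
world millimetres; axis *arguments* to R functions are 1-based.

# Mask fusion

Candidate lesion masks are fused by voxel-wise majority voting: a voxel is
lesion only when a strict majority of models agree (two of three in the
reference configuration). Ties at even counts resolve to non-lesion, which
keeps the rule conservative, and a single candidate passes through unchanged
(the single-model configuration). The vote is bounded between the voxel-wise
intersection and union of its inputs, is permutation-invariant and monotone;
these properties are asserted in the test suite.

# Morphological descriptors

*Volume* is the positive-voxel count times the physical voxel volume,
reported in mL. *Sphericity* \(\pi^{1/3}(6V)^{2/3}/A\) and *compactness*
\(A^3/(36\pi V^2)\) are computed from volume and surface area in consistent
units (mm³ and mm², with mL only at the reporting boundary); they satisfy
compactness = sphericity⁻³ identically. *Elongation* is
\(\sqrt{\lambda_3/\lambda_1}\) of the covariance of lesion voxel centers in
world millimetres — the ratio of minor to major principal axis length. A
single voxel is defined as elongation 1; a mathematically degenerate mask
(a perfect rod) scores 0, the exact covariance value.

**Surface area.** The mask's 0.5 iso-surface is triangulated by a
marching-tetrahedra mesher (each cell split into six tetrahedra sharing the
main diagonal, vertices linearly interpolated on cell edges) and triangle
areas are summed in physical coordinates. Meshing *raw* binary data produces
a staircase surface whose area is biased high by roughly 10–30% regardless
of resolution, so the mask is first anti-aliased with a separable Gaussian
(`sigma`, in voxel units). The default `sigma = 1.25` was calibrated against
the analytic sphere: it makes the signed error a smooth function of feature
size that shrinks monotonically with radius (about 3.3%, 1.3%, 0.6% and 0.2%
sphericity error at radii 10, 15, 20 and 30 voxels). Smaller bandwidths
leave oscillating staircase residue; larger ones round off genuine surface
detail (convex edges and corners are already smoothed — a digital cube
measures closer to a rounded cube, which is why closed-form checks of the
cube identity use analytic V and A rather than the mesher). If the smoothed
field never crosses the iso-level (a lesion a voxel or two across), the raw
binary field is meshed instead, so the area stays positive and finite down
to a single voxel. The mask is zero-padded internally so boundary-touching
lesions close their mesh.

**Solidity.** The convex hull is taken over the corner points of boundary
voxels' cubes, i.e. the hull of the voxelized solid itself, computed by an
incremental hull in C++ (the center cloud is first reduced to its hull
vertices; the hull of a union of congruent cubes equals the hull of those
vertices dilated by the cube, a Minkowski-sum identity). This convention
guarantees solidity ≤ 1 for every mask and makes the quantity well defined
down to one voxel. The cost is a half-voxel hull inflation for small
objects: a digital ball of radius 15 voxels scores about 0.896, reaching
0.92 by radius 20. A hull over voxel *centers* would avoid the inflation but
can exceed 1 by large margins on small convex lesions, which we considered
the worse failure mode.

# Spatial and intensity descriptors

The *intensity-weighted centroid* is the per-axis mean of lesion voxel
indices weighted by ADC intensity (ADC is used consistently wherever the
formulas need an intensity; it is the only quantitative map assumed
available for every subject). If in-mask intensities sum to a non-positive
value the unweighted centroid is used with a warning. *Maximum* and
*average* intensity are taken over lesion voxels, the average's denominator
being the lesion voxel count.

*Quadrants* split the volume by two index midplanes at half the array
extent: the left/right axis (default axis 1) and a second axis defaulting to
axis 3. The printed defaults follow the array-axis convention of the
formulas they implement; after RAS reorientation axis 3 is typically
inferior–superior rather than anterior–posterior, so both axes are
configurable (`quadrantConfig()`) and the choice is deliberately not
"fixed" silently. Indices strictly below the midplane count as Left /
Anterior. Fractions sum to one and the dominant quadrant is the argmax
(first label LA, LP, RA, RP on ties).

# GLCM texture protocol

Texture is measured on ADC intensities strictly inside the lesion, slice by
slice along the axial axis. In-lesion intensities are min–max scaled to 256
grey levels (`floor(255·(v−min)/(max−min))`; a constant lesion maps to level
0). Scaling is per subject over the whole 3D lesion by default —
"independent" normalisation is read as per-subject; a per-slice switch
exists (`glcmConfig(perSliceNormalization = TRUE)`) because the protocol
wording admits both readings.

For every slice containing lesion voxels, grey-level co-occurrence matrices
are accumulated for pixel distances d = 1, 2, 3 and directions 0°, 45°, 90°,
135°. A pixel pair contributes only when **both** pixels are inside the
lesion mask. Matrices are made symmetric (transpose added) and normalised to
probabilities. From each matrix six Haralick statistics are computed exactly
as printed: contrast Σ(i−j)²p, dissimilarity Σ|i−j|p, homogeneity
Σp/(1+|i−j|) (the absolute-difference form, not the squared-difference
inverse difference moment some libraries use), ASM Σp², energy √ASM, and
correlation from the marginal means and SDs with the limit convention
correlation = 1 whenever σᵢσⱼ < 1e−12 (constant regions). Shannon entropy
(base 2, 0·log0 = 0) comes from the slice's 256-bin level histogram, not
from the GLCM.

Feature values are averaged uniformly over the four directions and the
three distances — the distance average is a package choice, made so that the
protocol yields exactly seven values per slice; with uniform weights the
order of averaging is immaterial, which is why uniform weights were chosen.
Per-distance values remain available (`perDistance = TRUE`). Offsets (or
slices) with zero valid pairs are excluded from the corresponding averages
rather than contributing zeros. Patient-level features are the arithmetic
mean over contributing slices. If no slice yields a single valid pair the
texture block is undefined and recorded as missing.

Two implementations coexist deliberately: the transparent path
(`glcmSlice()` returning a dense `GLCMatrix`, `haralickFeatures()`) and a
sparse C++ path used inside `lesionTexture()` for speed. The test suite
asserts their exact equality and checks both against an independent
brute-force pair-enumeration oracle to 1e−10.

# Tract overlap

For each hemisphere, `overlapMetrics()` reports tract volume, the volume of
lesion ∩ tract, and the overlap percentage 100·V_overlap/V_tract. The
denominator is the *tract* volume — both conventions exist in the
literature, so this is stated explicitly. When grids differ, tract masks are
resampled onto the lesion grid by nearest neighbour (never the reverse;
binary structure is preserved by construction), and volumes use the lesion
grid's voxel volume. An empty tract after resampling yields a missing value
for that side rather than an error. Bilateral lesions are reported
symmetrically; lateralisation is left to downstream consumers.

# Cohort assembly

`extractSubject()` composes the stages into one record per subject: 19 named
features whose fixed vectorized expansion has 26 columns (centroid → 3,
quadrant distribution → 4, CST volume → 2, CST overlap → 2, all others 1).
The named count honours the feature registry; the expansion keeps the design
matrix well defined. Degenerate cases never abort a cohort run: an empty
fused lesion yields volume 0, missing shape/intensity/texture values and 0%
overlaps, with a warning. Records carry the hash of the extraction
configuration, and tables with different hashes refuse to concatenate.
Labels attach from a subject→mRS table; unlabeled rows are flagged and
excluded from outcome modelling, and the binary outcome is unfavourable iff
mRS > 2. The mRS horizon (discharge versus 24 h) is treated as an opaque
property of the label file.

# Outcome modelling protocol

The protocol enforces a strict information barrier around the held-out set:

1. **Stratified split.** The labeled cohort is split once into training and
   held-out subsets (`ceiling(n·0.2)` test subjects, largest-remainder
   allocation across classes, so 97 subjects give 77/20). The held-out set
   is used exactly once, for the final evaluation.
2. **Imputation.** Missing feature cells (degenerate subjects) are filled
   with training-set medians.
3. **Selection.** Per-column one-way ANOVA F statistics are computed on
   training rows only and aggregated to the 19 named features by taking
   each feature's best column (a multi-component feature is as informative
   as its strongest component). The top 17 named features are retained,
   ties breaking toward the lower registry index for determinism.
4. **Training.** Grid search over a small hyperparameter grid with
   stratified 5-fold cross-validation on the training set; the selection
   criterion is mean CV F1 at the 0.5 threshold (the criterion itself is a
   package choice). The winner is refit on the full training set. The
   default family is a random forest; a gradient-boosted alternative is
   available when the xgboost package is installed. The default grids are
   documented in `modelConfig()` and are not claimed to match any
   particular published configuration.
5. **Evaluation.** Accuracy, precision, recall, F1, ROC-AUC and Matthews
   correlation from the held-out predictions, with 95% bootstrap percentile
   confidence intervals over 1000 resamples of the held-out predictions
   (resampling the test set, not refitting — refitting would contradict the
   single use of the held-out set). Resamples on which a metric is
   undefined are skipped and counted. With no positive predictions,
   precision is 0 by convention; a single-class test set leaves ROC-AUC
   missing while the other metrics are still reported.
6. **Importance.** Impurity importance from the fitted trees and
   permutation importance (mean drop in held-out AUC over column shuffles,
   computed on held-out data only).

Every function that touches data during model development can report the
row identifiers it received through an audit hook
(`modelConfig(auditHook = ...)`); the test suite uses this instrumentation
to prove that selection and cross-validation never read held-out rows.

# The phantom generator

The built-in generator exists so that every stage — and the pipeline end to
end — is testable without clinical data. It is a geometric phantom, not an
anatomical simulation. Defaults define the study conditions used throughout
the tests and the acceptance script and were fixed by calibrating against
the generator's *own* truth records before any pipeline-level testing:

* **Grid**: 40×46×30 voxels at 2 mm isotropic — a deliberately scaled-down
  head-sized field of view keeping a cohort of hundreds of subjects
  tractable on one CPU.
* **Tracts**: two curved tubes (radius 3.5 mm, lateral offset ±16 mm from
  the midplane, sinusoidal bow 5 mm) running along the slice axis,
  symmetric and disjoint across the midplane — CST-shaped stand-ins with
  realistic volume (~2 mL at this scale).
* **Lesion**: one ellipsoid per subject, semi-axes uniform in 6–16 mm with
  a random rotation; placement is biased toward a tract centerline
  (probability 0.75, Gaussian jitter SD 5 mm) so the overlap distribution
  spans 0–60%.
* **ADC**: background 1100 ×10⁻⁶ mm²/s with spatially correlated noise
  (white noise smoothed at a 3 mm length scale, SD 70) and a −450 shift
  inside the lesion — ADC-dark infarct core with non-degenerate texture.
  The correlated field is generated around the lesion; all intensity and
  texture features read in-lesion voxels only.
* **Segmentation noise**: the three candidate masks are the truth eroded by
  one voxel, unchanged, and dilated by one voxel, each with 2% voxel flips
  in a two-voxel boundary shell — a crude but effective model of
  inter-model disagreement for exercising majority voting.
* **Outcome**: logit P(unfavourable) = β₀ + β₁·V_mL + β₂·mean overlap %.
  The strong-signal preset (β₀ = −4.5, β₁ = 0, β₂ = 0.45) was chosen so
  that the generator's own logits have a Bayes AUC of about 0.96 at roughly
  balanced prevalence — an overlap-dominated outcome a competent pipeline
  should recover. The null preset sets all coefficients to zero, making
  labels independent of the images. mRS labels are drawn uniformly from
  0–2 (favourable) or 3–6 (unfavourable) consistent with the binary label.

What the phantom does **not** emulate: real brain anatomy and vascular
territories, MR acquisition physics and artefacts, multi-focal or
non-ellipsoidal lesions, partial-volume effects at lesion borders, and
correlations between lesion appearance and outcome beyond the stated
logistic model. Passing the recovery tests therefore shows that the
pipeline measures what it claims and that signal present in its features is
found by its models — not that these features predict outcomes in real
cohorts.

# Problem sizes in tests and the acceptance script

The test suite checks signal recovery on 50 generator seeds of 300-subject
cohorts for each of the strong and null conditions; the acceptance script
reports the same quantities over 12 seeds per condition plus one cohort
evaluated with full bootstrap confidence intervals, alongside the registry,
protocol and bookkeeping counts. These sizes are the package's choice of a
desk-scale experiment: large enough that the mean held-out AUC has a
standard error near 0.01, small enough to run routinely.

# Known limitations

* Surface area and the shape indices built on it inherit the anti-aliasing
  trade-off: sub-voxel surface detail is smoothed away, and lesions only a
  few voxels across fall back to the staircase mesh, whose area is biased
  high (equivalently, their sphericity can exceed 1).
* Solidity carries the half-voxel hull inflation described above; on
  lesions under ~10 voxels across it is a conservative (low) estimate.
* The mask is treated as one lesion; no connected-component analysis is
  performed, so multi-focal masks are measured as a single object.
* Texture features are 2D slice-wise by design; no 3D co-occurrence,
  wavelet or fractal descriptors.
* The outcome protocol is exploratory: no model-comparison hypothesis
  tests, no calibration analysis, no ordinal mRS modelling.
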