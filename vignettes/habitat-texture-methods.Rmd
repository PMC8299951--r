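---
title: "Kinetic habitat texture analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic habitat texture analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(habitex)
```

This vignette documents the science inside `habitex`: the models each stage
assumes, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the numerical choices made where a
published description left the design open.

## 1. The analysis model

The pipeline assumes single-slice dynamic breast MRI: a pre-contrast image
and eight post-contrast phases. Its core hypothesis is that lesions are
kinetically heterogeneous — different pixels reach peak enhancement at
different times — and that texture computed *within* kinetically coherent
habitats carries more diagnostic signal than texture pooled over the whole
lesion, where between-habitat intensity differences act as nuisance
variation.

Pixelwise relative enhancement is

$$H(m,n,t) = \frac{I(m,n,t) - I(m,n,t_0)}{I(m,n,t_0)},$$

and the time to peak is the earliest phase attaining the maximum,
$\mathrm{TTP}(m,n) = \arg\max_t H(m,n,t)$. Lesion pixels with TTP in phases
1–4, 5–6 and 7–8 form the early, moderate and late habitats. Two numerical
guards matter here:

* **Zero baselines.** $H$ is undefined where $I(t_0)=0$; the denominator is
  clamped at $\delta = 1$ gray level. Clamping preserves the phase ordering
  of each pixel's curve, which is all the TTP map uses.
* **Ties.** A tied argmax resolves to the earliest phase, keeping "time to
  peak" the *arrival* time of the peak. Any strictly increasing transform
  of a pixel's curve leaves the partition unchanged (tested).

Empty habitats are legal: their feature vectors are emitted as missing and
the affected patient is excluded from that habitat's model only, with the
exclusion counted. The same policy covers habitats too small to support
some co-occurrence offset.

## 2. Segmentation

Segmentation operates on the fourth-phase subtraction image — the phase the
protocol singles out for reading — inside a region of interest standing in
for a radiologist's hand-drawn ROI (for synthetic data: the truth bounding
box padded by 10 pixels). ROI gray levels are normalized to $\mu \pm
3\sigma$ and quantized to 8 bits with round-half-up; rounding is fixed so
that results are bit-reproducible.

The clustering is a spatial fuzzy C-means: standard FCM memberships on the
quantized gray levels, but after every membership update each cluster's
membership image is smoothed with a local mean window before normalization,
which suppresses isolated misclassified pixels. Defaults (all overridable
through `spatial_fcm()` / `pipeline_config()`):

| parameter | default | rationale |
|---|---|---|
| clusters | 2 | lesion vs background within the ROI |
| fuzzifier m | 2.0 | the standard FCM choice |
| window | 3×3 mean | smallest neighborhood that regularizes contours |
| tol / max_iter | 1e-5 / 100 | membership changes, not centroid drift |
| centroid init | 64, 192 (even grid on 0–255) | deterministic: no run-to-run variance, no seed sensitivity |

The candidate mask (brightest-centroid cluster) is refined by keeping the
largest 4-connected component, filling interior holes, opening with the
3×3 cross, and keeping the largest component again so the result is a
single connected lesion. The published description names the steps but not
their order or connectivity; 4-connectivity and this order make the
refinement idempotent in practice and are frozen by tests.

## 3. The 467-feature schema

Per region: 4 histogram moments (population variance; skewness/kurtosis 0
by convention for constant regions; kurtosis non-excess), 380 co-occurrence
statistics, 44 run-length statistics, 39 wavelet magnitudes.

**Co-occurrence block.** The printed total of 380 does not equal 19
statistics × 4 angles × 4 distances = 304. The schema reconstructs 380 as
19 × (16 directional maps + 4 angle-averaged maps, one per distance) = 380
— the only enumeration consistent with both the total and the stated angle
and distance sets. The angle-averaged value is the statistic *of the
averaged matrix* (names carry the `amean` token). Matrices are symmetric,
normalized, and count only pairs whose both pixels lie inside the region
mask. Level indices run 1..L; entropies use the natural log with
$0\log 0 = 0$; sum variance is computed about the sum average; correlation
and the information measure of correlation fall back to 0 for single-level
regions. Name mapping of four idiosyncratic labels to the standard
catalog: cluster shadow → cluster shade, sum of square → sum of squares
(variance), difference square → difference variance, information measure
of correlation → IMC1.

Gray levels default to the full 8-bit range (`levels = 256`), faithful to
the quantization step; the knob exists because 256-level matrices are
sparse on very small lesions.

**Run-length block.** Maximal constant-gray runs along each of the four
angles at distance 1, truncated at mask boundaries. "Fraction of image in
runs" is interpreted as run percentage (runs over region pixels); the
alternative normalizations differ only by constant factors on rectangular
regions.

**Wavelet block.** The masked bounding box is filled with the region mean
outside the mask, padded with the region mean to the next multiple of 16
(mean padding rather than zeros, to avoid injecting boundary energy the
mean-fill is there to suppress), and decomposed over 4 levels with Haar,
Daubechies-2 and Symlet-4 orthonormal filter banks. Each of the 12 detail
subbands contributes its mean absolute coefficient; the 13th value per
family is the scale-4 approximation magnitude — the single unnamed
parameter in the published count, read here as the approximation subband.
Default boundary handling is half-sample symmetric reflection; a
periodized mode exists and is exactly orthonormal on dyadic patches
(Parseval identity, used as a test oracle). The magnitude statistic keeps
subband features in gray-level units, consistent with the scale of
published per-feature summaries.

## 4. Selection and classifiers

Zero-variance features are removed first (correlation undefined), then a
greedy scan in canonical schema order removes the *later* feature of any
pair with $|r| > 0.95$ — determinism requires an order convention and the
schema order is the only canonical one. LASSO selection fits an
L1-penalized logistic path on z-scored training features; the penalty is
chosen at minimum 10-fold cross-validated deviance rather than the 1-SE
rule, the less conservative choice consistent with selected-set sizes in
the mid-teens. An empty selection is legal and flagged; downstream such a
model scores all patients identically (chance level).

The decision tree is CART with the Gini index, grown full and pruned at
the complexity parameter minimizing internal 10-fold cross-validated
error. The SVM uses the RBF kernel — the published account of mapping to a
higher-dimensional space implies a nonlinear kernel — with $(C, \gamma)$
chosen by stratified inner 10-fold CV AUC over $C \in \{0.1, 1, 10, 100\}$
and $\gamma \in \{1/p, 0.01, 0.1, 1\}$. Each region (whole/early/
moderate/late) gets its own prefilter → LASSO → DT/SVM pipeline, giving
the 8 models of the evaluation report.

Training-cohort ROC metrics are reported from pooled out-of-fold CV scores
(leakage-free); resubstitution metrics of the refit model are also
emitted, labeled, since published training metrics could be either.
Validation cohorts are scored by the refit model and summarized at the
training-derived Youden threshold — the defensible leakage-free choice
when no threshold rule is stated. Raw p-values are reported without
multiple-testing correction, flagged as such in the report object.

## 5. The synthetic generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, not MR physics:

* **Geometry.** Irregular star-shaped lesions (Fourier-perturbed ellipses)
  covering 1–25% of a 128×128 grid; one 4-connected component.
* **Kinetics.** Each lesion pixel follows a piecewise-linear rise to its
  peak enhancement exactly at its injected TTP phase, then geometric
  washout — the simplest curve family whose argmax is identifiable.
  Injected TTP phases are spatially coherent (quantile-binned smooth
  random field), so habitats form patches, as real habitats do.
* **Texture.** The per-pixel peak enhancement is modulated by zone-wise
  Gaussian random fields. Class differences live in the early and late
  habitats (malignant: shorter correlation length, higher amplitude);
  moderate-habitat texture is class-identical.
* **Nuisance structure.** Per-patient draws — TTP-mixture jitter, shared
  base roughness, per-habitat intensity gains, enhancement midpoint,
  washout rate, image noise level — overlap the classes and, crucially,
  scramble the *whole-lesion* view: whole-region co-occurrence statistics
  mix randomly offset habitats, while within-habitat statistics are
  robust to those offsets. This is the mechanism by which the generator
  reproduces the qualitative ordering (habitat models, especially early
  and late, beat whole-tumor models; SVM at least matches the tree) at
  realistic AUC magnitudes rather than saturating at 1.0. The preset
  magnitudes were chosen to land validation AUCs in the high-0.7s to
  low-0.9s; per the scenario design, only this qualitative ordering —
  not any specific AUC value — is asserted anywhere.
* **Scenarios.** `default` as above; `strong` widens every class gap;
  `null` draws both classes from identical settings, the negative control
  under which every model must stay near chance.
* **Scanner split.** The validation cohort carries a mild scanner
  surrogate (6% baseline gain, 15% more noise); cohorts are split by this
  tag, never randomly.

What the generator does **not** emulate: coil profiles, k-space artifacts,
partial-volume fat suppression, 3D structure, biological correlations
between lesion size and class. Passing tests therefore demonstrate the
pipeline's correctness and the internal consistency of the
habitat-vs-whole comparison on data with planted structure — not clinical
performance.

## 6. Statistical toolkit

AUC variance and paired AUC comparisons use the DeLong
structural-components method (`pROC` supplies the estimator; independent
pair-counting and permutation oracles check it in the tests). Confidence
intervals are the normal approximation $\mathrm{AUC} \pm 1.96\,SE$ clipped
to $[0,1]$. Identical paired score vectors return p = 1 by convention.
Normality screening uses the Lilliefors-corrected Kolmogorov–Smirnov test
(plain KS with estimated parameters is anti-conservative); p ≥ 0.05 routes
a variable to mean±SD summaries, otherwise median±IQR, with zero-variance
samples non-normal by convention. Reader agreement uses ICC(2,1) — two-way
random effects, absolute agreement, single measures — computed from the
ANOVA decomposition.

## 7. Problem sizes and determinism

Default experiments use the reference cohort sizes (84/125 training,
40/50 validation) on 128×128 grids; the test suite's end-to-end checks run
exactly those sizes, and its exhaustive oracles cover all 65,536 binary
4×4 images and all score orderings up to length 8. Every random draw flows
from a single configuration seed through derived substreams (generator,
folds, models); fixed seed implies a bit-identical cohort and an identical
evaluation report, which the suite asserts by re-running the pipeline.

## 8. Known limitations

* Single-slice 2D analysis only; no 3D texture.
* The 380-count co-occurrence enumeration is a reconstruction (see §3).
* The spatial FCM variant (mean-window membership smoothing) is one of
  several published spatial-FCM schemes; any variant satisfying the same
  contract would do.
* Univariate Wald p-values are unreliable under complete separation; the
  fit flags them rather than suppressing the feature.
* Synthetic calibration targets the qualitative ordering of models, not
  effect sizes; absolute AUCs on real cohorts are out of reach by design.
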