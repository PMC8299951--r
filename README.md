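# habitex — intratumoral habitat texture analysis for breast DCE-MRI

`habitex` implements a complete, tested pipeline for differentiating benign
from malignant breast lesions on dynamic contrast-enhanced MRI (DCE-MRI) by
partitioning each lesion into **kinetic habitats** and classifying texture
features extracted from each habitat. It is aimed at radiomics researchers
who want a reproducible, desk-scale implementation of the subregion-texture
approach, complete with a synthetic cohort generator that provides ground
truth for every stage.

## The method

Each patient contributes a single-slice dynamic series: one pre-contrast
image `I(m,n,t0)` and eight post-contrast images `I(m,n,t)`, `t = 1..8`.

1. **Segmentation.** The phase-4 subtraction image (`post4 − pre`) is
   normalized inside a reader-style ROI to `μ ± 3σ`, quantized to 8
   bits/pixel, clustered with a spatial fuzzy C-means (memberships smoothed
   by a 3×3 window each iteration), and refined morphologically
   (largest 4-connected component → hole filling → 3×3-cross opening).
2. **Kinetic habitat partition.** Pixelwise relative enhancement
   `H(m,n,t) = (I(m,n,t) − I(m,n,t0)) / I(m,n,t0)` and its time to peak
   `TTP(m,n) = argmax_t H(m,n,t)` split the lesion into **early** (TTP 1–4),
   **moderate** (TTP 5–6) and **late** (TTP 7–8) subregions.
3. **Texture extraction.** For the whole lesion and each subregion, 467
   features: 4 histogram moments; 380 gray-level co-occurrence statistics
   (19 statistics × 4 angles × 4 distances, plus the angle-averaged matrix
   at each distance); 44 run-length statistics (11 × 4 angles, distance 1);
   and 39 wavelet subband magnitudes (Haar, Daubechies-2, Symlet-4 × 13
   subbands over 4 scales).
4. **Modeling.** Pearson prefilter (`|r| > 0.95` drops the later feature),
   LASSO-penalized logistic selection (penalty by 10-fold cross-validated
   deviance), then a CART decision tree and an RBF-kernel SVM per region,
   tuned and scored with stratified 10-fold cross-validation.
5. **Evaluation.** DeLong AUC confidence intervals, paired DeLong tests
   between models, Youden operating points (training-derived thresholds
   applied to validation), Lilliefors normality screening, univariate
   logistic AUC, and ICC(2,1) agreement.

Because clinical DCE-MRI cohorts are rarely shareable, the package ships a
synthetic generator (`generate_cohort()`) producing lesions with known
masks, known per-pixel TTP and class-dependent subregion texture, so every
stage can be validated against ground truth.

## Worked example

```r
library(habitex)

# one synthetic malignant study with ground truth
mask  <- generate_lesion(seed = 1, grid = c(128, 128))
kin   <- kinetic_params(noise_sd = 0)
ttp   <- assign_ttp(mask, kin$ttp_mixture, seed = 2)
study <- generate_study(mask, ttp, kin, seed = 3)

seg <- segment_study(study)                      # FCM segmentation
dice_coefficient(seg$mask, mask)
#> [1] 0.9921722

tt <- time_to_peak(relative_enhancement(study), seg$mask)
partition_subregions(tt, seg$mask)
#> Kinetic subregion map: 1014 lesion pixels
#>   early (TTP 1-4):    510
#>   moderate (TTP 5-6): 257
#>   late (TTP 7-8):     247

fv <- extract_features(seg$qroi$patch, seg$qroi$roi_mask)
length(fv)
#> [1] 467
```

The printed Dice coefficient compares the fuzzy-C-means mask against the
generator's truth mask; the subregion counts show the partition of the
recovered lesion by time to peak; `fv` is the canonical 467-feature vector.

A full experiment — two scanner-split cohorts (84/125 training,
40/50 validation), per-region models, evaluation report — is one call:

```r
res <- run_pipeline(pipeline_config(seed = 17))
subset(res$report$performance, cohort == "validation",
       select = c(model, auc))
#>           model       auc
#>        DT_Whole 0.7175000
#>       SVM_Whole 0.8040000
#>        DT_Early 0.8205000
#>       SVM_Early 0.8930000
#>     DT_Moderate 0.7325000
#>    SVM_Moderate 0.8280000
#>         DT_Late 0.6979950
#>        SVM_Late 0.8596491
```

Models built on the early and late kinetic habitats outperform the
whole-tumor models, and the SVM outperforms the decision tree — the
qualitative pattern the pipeline is designed to expose.

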