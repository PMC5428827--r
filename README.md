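# deltarad

Delta-radiomics feature extraction and longitudinal survival modeling
for CT imaging of solid tumors.

## The problem

Patients with locally advanced non–small cell lung cancer (NSCLC) are
imaged weekly with 4DCT during chemoradiation. Quantitative imaging
features ("radiomics") computed from the pretreatment scan are known to
carry prognostic information; the question this package's pipeline
addresses is whether the *changes* in those features over the course of
therapy — **delta-radiomics** features — add prognostic value beyond
clinical factors and pretreatment radiomics.

The pipeline implements, as tested and reusable code:

1. **Feature extraction.** 65 base features per scan — 16 shape, 11
   intensity-histogram, 22 gray-level co-occurrence (GLCM), 5
   neighborhood gray-tone difference (NGTDM), 11 run-length (RLM) —
   from a 3D HU volume and tumor ROI mask, each texture/intensity
   feature under four preprocessing variants (ROI thresholding to
   −100..200 HU; Butterworth smoothing of order 2, cutoff 125; 8-bit
   depth resampling, bin width 16 HU; both), giving
   49 × 4 + 16 = 212 feature/preprocessing combinations.
2. **Feature-specific preprocessing selection.** Per combination: a
   univariate Cox screen for overall survival (keep p < 0.10), a
   Wilcoxon rank-sum scanner-dependence screen on week-1 scans (drop
   p < 0.05), and a Spearman volume-correlation tie-break (smallest
   |ρ| wins).
3. **Delta-radiomics.** A random-intercept mixed model
   `feature ~ dose + (1 | patient)` screens for dose-driven change
   (ML fit, likelihood-ratio test, Benjamini–Hochberg across
   features), then per patient:
   `relativeNetChange = (F_weekFinal − F_week1) / F_week1`, the OLS
   slope of the feature on cumulative dose, and the last-week value.
4. **Survival modeling.** Landmark analysis (day 90 from trial entry);
   nested Cox models built by bidirectional stepwise AIC with forced
   nesting inside leave-one-out cross-validation (model 1 clinical,
   model 2 + pretreatment radiomics, model 3 + delta-radiomics);
   covariates selected in > 50 % of iterations retained; unbiased
   LOOCV risk predictions; Harrell's c-index; median-split
   Kaplan–Meier stratification with the log-rank test; nested
   likelihood-ratio tests.

Because the study's patient images are not publicly deposited, the
package ships a **synthetic cohort generator** that emulates the study
conditions — weekly exhale-phase 4DCT tumor volumes (1 × 1 × 2.5 mm
grid), two-scanner acquisition with an HU offset, dose-dependent tumor
shrinkage and texture homogenization, and exponential
proportional-hazards outcomes with planted covariate effects — so every
stage of the analysis can be validated by parameter recovery.

## Worked example

```r
library(deltarad)

cfg <- cohort_config(60, seed = 42)   # n = 60, planted effects 0.8/SD
run <- run_pipeline(cfg, endpoint = "OS")
print(run)
#> deltarad pipeline run (OS, tabular mode, n = 60)
#> exclusions: volume 0, protocol 0, early_event 0, retained 60
#> model 1: (null)
#>   c-index 0.500, log-rank p NA
#> model 2: shape_compactness2_Week0
#>   c-index 0.763, log-rank p 9.49e-07
#> model 3: shape_compactness2_Week0 + ngtdm_strength_Slope
#>   c-index 0.800, log-rank p 3.36e-09

selection_frequency(run$freq, "shape_compactness2_Week0", level = 2)
#> [1] 1
selection_frequency(run$freq, "ngtdm_strength_Slope", level = 3)
#> [1] 0.9166667
```

Reading the output: on this synthetic cohort the clinical factors alone
are not prognostic (c-index 0.5, the null model). Adding the planted
pretreatment shape covariate (`shape_compactness2`, selected in 100 %
of LOOCV iterations) raises the c-index to 0.76, and the planted
delta-radiomics slope (`ngtdm_strength_Slope`, the per-Gy
texture-strength trend, selected in 92 % of iterations) raises it
further to 0.80 with a strongly significant median-split Kaplan–Meier
stratification — the intended recovery of both planted effects.

Individual stages are exposed directly, e.g.:

```r
fx <- generate_fixture("sphere_r10")
shape_features(fx$mask, fx$spacing)[["shape_compactness2"]]
#> [1] 0.9843889

bh_adjust(c(0.01, 0.02, 0.04))
#> [1] 0.03 0.03 0.04
```

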