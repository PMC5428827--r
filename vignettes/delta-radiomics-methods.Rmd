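---
title: "Delta-radiomics methods: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta-radiomics methods: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltarad)
```

This vignette is the package's account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical
choices, and the known limitations.

## The analysis in one paragraph

Weekly CT scans of a tumor during radiotherapy yield, per patient, a
longitudinal series of radiomics feature values. The pipeline (i)
chooses, per feature, the image preprocessing under which the feature
is prognostic but not scanner-dependent; (ii) identifies features whose
weekly values change with delivered dose; (iii) condenses each
patient's trajectory into three delta-radiomics covariates (relative
net change, dose-regression slope, last-week value); and (iv) asks, via
nested Cox models cross-validated at the patient level, whether the
delta covariates improve outcome prediction beyond clinical factors and
pretreatment radiomics.

## Feature extraction

### Preprocessing variants

Every texture/intensity feature is screened under four variants:

| variant | steps |
|---|---|
| `raw` | ROI thresholding only |
| `smooth` | thresholding + Butterworth smoothing |
| `resample8` | thresholding + 8-bit depth resample |
| `smooth_resample8` | thresholding + smoothing + resample |

*Thresholding* restricts the ROI mask to voxels in the inclusive HU
window [−100, 200], excluding normal lung and bone from the contoured
gross tumor volume. It removes voxels from the mask; image values are
never clipped, so boundary voxels seen by the smoothing filter keep
their true neighbors.

*Butterworth smoothing* applies the radial transfer function
$H(f) = (1 + (f/f_c)^{2n})^{-1/2}$ with order $n = 2$ in the 2D
frequency domain, slice by slice. Smoothing is 2D because axial slices
(2.5 mm) are much thicker than the in-plane voxel (≈1 mm); an isotropic
3D filter would mix scales. The cutoff constant 125 is interpreted as a
frequency index on the 512-sample axial reconstruction axis, i.e.
$f_c = 125/512$ cycles/sample (125/256 of Nyquist). The filter tooling
that motivated this setting leaves the unit unstated; the
reconstruction-matrix reading is the only one under which "cutoff 125"
is dimensionally meaningful, and the choice only rescales how
aggressive the smoothing is. DC gain is exactly 1, so mean HU is
preserved.

*Bit-depth resampling* maps the 12-bit CT range [−1024, 3071] linearly
onto $2^{\text{bits}}$ levels; at 8 bits the bin is 16 HU wide, so
neighboring-level differences reflect density changes rather than
noise. For texture matrices on *unresampled* variants the gray axis
uses 16 HU-wide bins over the threshold window (19 bins), mirroring the
same rationale; 1 HU bins would make the co-occurrence matrix an image
of the noise.

### The registry

The 65-feature registry (16 shape, 11 intensity, 22 GLCM, 5 NGTDM, 11
RLM) follows the canonical Haralick, Amadasun–King and Galloway sets at
exactly those category counts; the category counts, not the identity of
every 22nd co-occurrence statistic, are the testable contract, and the
three features singled out as prognostic in this literature
(compactness2, run-length gray-level non-uniformity, NGTDM texture
strength) are guaranteed present. Texture matrices are 3D: the 13
unique directions at distance 1, accumulated symmetrically into a
*single* matrix (not averaged per direction), matching the default of
the feature-extraction tooling this registry models. NGTDM uses the
26-connected neighborhood restricted to the mask, excluding voxels with
no in-mask neighbor; $\varepsilon = 10^{-6}$ guards its denominators,
so a perfectly homogeneous region saturates coarseness at
$1/\varepsilon$ and has strength 0. The strength numerator is
$\sum_{i,j} p_i p_j (i-j)^2$ (the product-weight form).

### Shape and the isoperimetric ratios

Shape describes the clinical contour: it is computed from the
undeformed mask without HU thresholding or preprocessing. Two volume
conventions coexist deliberately:

* `shape_volume_cm3` / `shape_voxel_count` are voxel counts — the ROI
  volume convention used by the small-ROI exclusion rule;
* the compactness/sphericity family uses the **same triangulated
  isosurface** for both area and volume. The mask is Gaussian-smoothed
  (σ = 1 voxel) to remove the voxelization staircase and its 0.5 level
  set is triangulated by marching tetrahedra; area is the summed
  triangle area and volume the divergence-theorem integral over the
  same closed mesh. Because both quantities refer to one closed
  surface, the isoperimetric inequality guarantees
  $\text{compactness2} = 36\pi V^2/A^3 \le 1$ for every body, with
  equality only for the ball. A digital ball of radius 10 voxels scores
  0.984, radius 40 scores 0.986; naive voxel-face area counting would
  instead overestimate $A$ by ~50 % for a sphere and bias compactness2
  to ~0.3, which is why mesh-based area is the default.

Axis lengths are $4\sqrt{\lambda_k}$ of the physical-coordinate
covariance eigenvalues; the maximum 3D diameter is evaluated on
boundary voxels (exact below 1 500 boundary points, directional extreme
points beyond, a convex-hull vertex subset whose error is negligible at
tumor scales).

## Screening and selection

The univariate Cox screen z-scores each feature (scale-free
coefficients, stable fits) and uses the likelihood-ratio test against
the null model — the "better fit than the null model" reading — at
p < 0.10, deliberately lenient and uncorrected because it steers
selection, not inference. The scanner screen is a two-sided Wilcoxon
rank-sum test on week-1 values (exact for combined n ≤ 20); a feature
is kept only when p > 0.05, i.e. when it does *not* track the scanner.
Among surviving variants the one with smallest |Spearman ρ| against
gross tumor volume wins; the absolute value is used because a strong
negative volume correlation is as much volume-redundancy as a positive
one, and ties fall back to the fixed variant order (raw, smooth,
resample8, smooth_resample8).

## Delta-radiomics

The dose-response screen fits
$\text{value} \sim \text{dose} + (1\,|\,\text{patient})$ by maximum
likelihood — ML, not REML, because the likelihood-ratio test compares
fixed-effects structures — and refers twice the log-likelihood
difference to $\chi^2_1$. Singular fits (zero between-patient variance)
fall back to the boundary model, which keeps the LRT valid. The
companion one-sample t-tests ask whether the cohort's relative net
changes and slopes differ from 0; all three p-value families are
Benjamini–Hochberg adjusted across features and a feature passes only
if all three are significant at 0.05.

Per patient, *week 1* is the first weekly intra-treatment scan (the
pretreatment scan is week 0 and enters models separately with the
`_Week0` suffix). The slope regresses the feature on **cumulative dose
(Gy)**, not on week index, for consistency with the dose covariate of
the mixed-model screen; the two differ only by the dose-per-week
factor when scans are evenly spaced, but dose is the biologically
meaningful axis when they are not. Missing weeks are simply omitted.
Delta covariates use the conventional suffixes `netPercentChange`,
`Slope`, `WeekLast`.

## Survival modeling

Landmark analysis measures time from 90 days after trial entry, so
that patients who must survive treatment to contribute weekly scans do
not bias the comparison; pre-landmark events are excluded upstream,
with the exclusion tally ordered volume → protocol → early event (the
order is a package convention; the rules themselves do not overlap in
the fixtures).

Stepwise AIC starts from the full scope (forced + all candidates) and
applies the single add/drop move that most decreases
$\mathrm{AIC} = -2\log L + 2k$ (partial likelihood, Breslow ties —
the common default, fixed here for reproducibility) until no move
improves; forced covariates are never droppable, which implements the
forced nesting of model 1 ⊂ model 2 ⊂ model 3. Determinism on tied
moves: drops before adds, then candidate order. The implementation is
move-for-move identical to the reference stepwise-AIC implementation
in the MASS package on the same data (verified in the test suite).

The leave-one-out loop runs the three-level build once per left-out
patient and tabulates selections; covariates above the strict 50 %
threshold are refit on all patients (a level that adds nothing reuses
the previous level's model, the null model at level 1, and the
likelihood-ratio test between identical models is reported NA).
Unbiased risk predictions then come from a second LOOCV with the
covariate sets frozen and only coefficients refit; the linear predictor
$x_i'\hat\beta$ is used uncentered so predictions are comparable across
folds. Harrell's c-index counts a pair as comparable when the earlier
time belongs to an observed event (time ties skipped) and scores
prediction ties 0.5; a null model therefore scores exactly 0.5.
Risk stratification splits at the median prediction, ties assigned to
the low-risk group, evaluated by the two-group log-rank test. The
median is used rather than an optimized cutoff precisely because no
independent validation set exists to keep an optimized cutoff honest.

### False-discovery behavior, honestly

Stepwise AIC retains a null covariate whenever its conditional
$\chi^2_1$ exceeds 2 (p ≈ 0.157), and because every LOOCV fold shares
n − 2 patients with every other, a chance full-data association is
*stable* across folds rather than averaged away. With on the order of
ten candidate covariates, at least one spurious covariate will clear
the 50 % filter in most null cohorts — in the package's own null
simulations at n = 60, essentially all of them. The >50 % filter
guards against fold-to-fold instability, not against multiplicity; a
covariate's selection frequency should be read as a stability
statistic, never as a calibrated error rate. This is why the planted
effects in the recovery studies are large (0.8 per SD): the claim the
tests support is that true strong effects are found and ranked above
the noise floor, not that the noise floor is empty.

## The synthetic cohort generator

The generator defines the study conditions the tests run under.

* **Clinical factors** are drawn independently from the marginal
  frequencies of the modeled 107-patient NSCLC population (sex 62/107
  male, age ≥65 62/107, T3–4 58/107, N2–3 83/107, stage groups
  12/44/49/2, squamous 46/107, smoking 34/64/9, pack-year bands
  20/37/28/22, KPS ≥90 52/107, prescription 74 Gy with probability
  72/107 and tied to the >70 Gy dichotomy). Joint dependence between
  factors is *not* emulated.
* **Latent structure.** Each patient has a standard-normal risk score
  and an independent standard-normal shape score. The response rate
  $\exp(-\text{risk}/2)$ (lognormal, mean ≈ 1) scales how fast that
  patient's tumor shrinks and homogenizes per delivered Gy, so the
  measured dose-slope of texture is a monotone image of the latent
  risk.
* **Outcomes** are exponential proportional hazards: the OS log-hazard
  is `beta_shape`·shape + `beta_delta`·risk + `beta_clinical`·T-stage
  (defaults 0.8, 0.8, 0.5); DM loads on shape and T stage, LR on risk
  only — mirroring the qualitative pattern that pretreatment shape
  drives survival/metastasis models while only an end-of-treatment
  texture covariate is prognostic for local recurrence. Baseline
  hazards give median OS ≈ 640 days past the landmark with lower DM
  and LR event rates; censoring is a single shared follow-up process
  per patient whose rate yields the configured OS censoring fraction
  (default 20 %).
* **Images** (image mode): a textured ellipsoid on a 64³ grid at
  1 × 1 × 2.5 mm — desk-scale while preserving slice anisotropy. The
  boundary is an ellipsoid level set perturbed by a smooth random
  field whose amplitude grows with the shape score, so surface
  irregularity (hence compactness2) is a planted, recoverable baseline
  covariate. Weekly masks are nested by construction (volume
  monotonicity under a positive shrink rate is exact, not
  statistical); interior texture amplitude decays with dose × response
  rate within HU ≈ −50..150; scanner B scans receive a +20 HU offset
  plus extra acquisition noise. Background is lung-like noise, not
  anatomy; there is no respiratory motion, no vasculature, no contour
  uncertainty.
* **Delta-stage gating differs between modes.** In image mode the
  delta screen only sees the features that survived preprocessing
  selection, the full gated flow in which a feature must already be
  prognostic pretreatment before its changes are considered. In the
  feature-level mode the generator deliberately makes the planted
  delta family's *baseline* outcome-independent (only its dose-slope
  carries risk), which is exactly the situation the gate would
  discard; tabular mode therefore sends all dose-responsive
  longitudinal features to the delta stage directly. This keeps the
  delta-recovery question testable while the image path preserves the
  gated design; the gate's cost — discarding features whose change,
  but not baseline, is informative — is a real property of the design
  worth knowing about.
* **Feature-level mode** (`generate_feature_tables()`) draws the
  feature tables directly from the same latent variables: a
  compactness2 surrogate linear in the shape score, one dose-responsive
  feature whose slope is proportional to the response rate (the planted
  delta family), one dose-responsive feature with an *independent*
  patient-specific rate, one with a common rate, one static feature,
  and pure-noise pretreatment features. Replicate model-recovery
  studies (25 cohorts of 60) run in this mode; voxel-level synthesis
  plus extraction of ~12 000 volumes is not a desk-scale computation,
  and the survival machinery is indifferent to where the covariate
  table came from. The image path is exercised end to end on small
  cohorts (n = 8, 32³ grids) in the test suite.

What passing tests therefore show: the implementation recovers known
planted structure through the entire pipeline under realistic effect
sizes, sample sizes, and censoring. What they do not show: performance
on real tumors, whose texture, contouring variability, scanner effects
and factor correlations are all richer than the generator.

## Numerical choices and degenerate inputs

* Problem sizes in the shipped tests/acceptance runs: n = 60 cohorts,
  25 replicates for recovery rates, 500 replicates for the
  mixed-model type-I error (30 patients × 7 weeks), digital balls up
  to radius 40 voxels.
* Texture matrices with fewer than 2 voxel pairs, no runs, or no
  neighbored voxels raise classed degenerate errors; an empty
  thresholded ROI during batch extraction flags the rows missing
  rather than aborting the cohort.
* Constant features: Cox screen p = 1 (flagged), Spearman ρ recorded 0
  (flagged), zero-variance t-test p ∈ {0, 1} by the sign of the mean
  (flagged); zero-variance skewness/kurtosis defined 0.
* The week-1 value 0 makes relativeNetChange undefined (missing);
  fewer than two weekly scans make the slope missing.
* Stepwise ties: drop before add, then candidate order; AIC
  improvements below 10⁻¹⁰ terminate the search.
* All generators take explicit seeds and restore the caller's RNG
  state; per-patient and per-stage seeds derive from the master seed,
  so any stage can be re-run independently and reproduces its outputs
  exactly.

## Limitations

* The registry's 22 GLCM and 16 shape identities are the canonical
  sets; other implementations may bin, aggregate or name differently,
  so absolute feature values are comparable only within this package.
* Spacing-anisotropic inputs are handled in physical coordinates for
  shape but texture offsets are lattice steps; a 2.5 mm slice step is
  treated as one "distance-1" neighbor like a 1 mm in-plane step, the
  standard (if crude) radiomics convention.
* No competing-risks modeling, time-varying covariates, feature
  harmonization across scanners, or isotropic resampling.
* The smoothing pre-filter for the isosurface slightly rounds
  high-curvature shape detail (corners of a cube); compactness of
  *smooth* bodies is accurate, and all ratio features are exact given
  V and A via `shape_ratio_features()`.
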