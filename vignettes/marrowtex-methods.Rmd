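---
title: "Methods: fat-fraction mapping and 3D texture analysis of vertebral bone marrow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fat-fraction mapping and 3D texture analysis of vertebral bone marrow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marrowtex)
```

marrowtex implements the full analysis chain of a cross-sectional quantitative
MRI study of lumbar vertebral bone marrow: chemical-shift-encoded (CSE) water-fat
signal modelling to proton density fat fraction (PDFF) maps, masked 3D texture
feature extraction on those maps, and the group-statistics stage that compares
features across vertebral levels, sexes and age groups. Because subject scans
from such studies are rarely shareable, the package also ships a synthetic
phantom/cohort generator with the same statistical structure, so the entire
pipeline is testable end to end from code alone.

## The water-fat signal model

A spoiled gradient-echo acquisition samples each voxel's complex signal at
echo times $TE_n = TE_1 + (n-1)\,\Delta TE$. marrowtex models that signal as

$$ s(TE_n) = \bigl(W + c_F(TE_n)\,F\bigr)\;
   e^{\,i 2\pi \psi TE_n}\; e^{-R_2^{*} TE_n}, $$

with nonnegative water and fat amplitudes $W, F$, a per-voxel field-map
frequency $\psi$ (Hz) and a single effective relaxation rate
$R_2^* = 1/T_2^*$ shared by both species. Fat is not a single resonance: the
dephasing coefficient

$$ c_F(t) = \sum_p \alpha_p\, e^{\,i 2\pi\, \gamma B_0\, \Delta\delta_p 10^{-6}\, t},
   \qquad \sum_p \alpha_p = 1 $$

sums over the triglyceride peaks at chemical shifts $\Delta\delta_p$ ppm
relative to water ($\gamma$ = 42.5775 MHz/T). The default spectrum
(`default_fat_spectrum()`) is a seven-peak table in the style of multi-peak
calibrations used for marrow and liver fat, with the dominant methylene
resonance split into its 1.30/1.60 ppm components; it is configuration data,
not code, and any normalized table can be substituted. The default echo train
(`acquisition_params()`) is an eight-echo 3 T spine protocol with
TR/TE1/$\Delta$TE = 11/1.4/1.1 ms and a 3° flip angle; at that flip angle T1
weighting is negligible, which is why the model (deliberately) carries TR and
flip angle as metadata only.

PDFF is the fat signal over the total signal, $100\,F/(W+F)$ percent — an
absolute, scanner-independent measure of marrow fat content.

### Fitting

`fit_water_fat()` estimates $(W, F, \psi, R_2^*)$ per voxel by variable
projection: for fixed $(\psi, R_2^*)$ the model is linear in $(W, F)$, and the
nonnegative two-parameter least-squares solution is available in closed form
(solve unconstrained; if a component is negative, the best single-species fit
is optimal). A coarse grid over $\psi$ (the unaliased range
$\pm 1/(2\Delta TE)$, 15 Hz steps) and $R_2^*$ (0-160 s$^{-1}$, 40 s$^{-1}$
steps) locates the global residual minimum — this is what resolves water-fat
swaps, since with a multi-peak spectrum the true solution has strictly
smaller residual than the swapped one — and Levenberg-Marquardt refinement
(via minpack.lm) polishes all four parameters to machine precision. A fit
that fails to improve on the grid solution is returned flagged
(`valid = FALSE`) rather than raising; all-zero input is an error.
Noiseless simulate-fit round trips recover parameters to $10^{-6}$ relative
across PDFF 0-100%, $\psi \in [-60, 60]$ Hz, $R_2^* \in [0, 150]$ s$^{-1}$
(this is asserted in the test suite), and `decompose_volume()` applies the
same fit voxelwise under a mask with PDFF clamped to $[0, 100]$.

## Texture features

Texture analysis runs on the PDFF map inside a per-vertebra mask, after two
preprocessing steps:

* **Isotropic resampling** (`resample_isotropic()`): trilinear for the map,
  nearest-neighbor for the mask (labels must stay integral). Isotropy is what
  makes the 13 diagonal offsets geometrically comparable
  ($\ell \in \{1, \sqrt2, \sqrt3\}$ voxel units); counts are not distance
  weighted.
* **Gray-level quantization** (`quantize_gray_levels()`): 100 equally sized
  bins by default, preventing co-occurrence sparseness. The default bounds
  are the fixed absolute PDFF scale (0, 100)% — PDFF is absolutely calibrated,
  so fixed bounds keep gray levels comparable across subjects — with a
  per-ROI min/max option (`bounds_mode = "roi_minmax"`) for parity with
  radiomics toolboxes that normalize to the gray levels present. The choice
  is recorded in every output row. A zero-range ROI maps to level 1 and the
  second-order features then take their analytic constant-image values.

**Global (first-order) features** (`global_features()`): variance, skewness
and excess kurtosis of the in-ROI intensity histogram. Moments are computed
from bin centers weighted by bin probabilities (bin count = the maximum of
the Sturges, Scott and Freedman-Diaconis rules — the most conservative
combination against sparseness; `method = "raw"` gives raw-sample moments).
Population denominators ($n$) are used. The kurtosis convention is *excess*
(Gaussian scores 0), chosen because reported marrow values of roughly 0.5-1.5
are consistent with excess kurtosis for near-Gaussian intensity
distributions; a zero-variance ROI flags skewness/kurtosis as undefined
rather than zeroing them.

**Second-order features** (`build_glcm()`, `glcm_features()`): the gray-level
co-occurrence matrix $p(i,j)$ is the joint probability of the gray levels of
two voxels separated by an offset $d$, both inside the mask, accumulated
symmetrically (each pair in both orders, so the marginals coincide and
correlation is well defined). Eight features are computed per direction:
energy $\sum p^2$, entropy $-\sum p \log_2 p$ (bits), contrast
$\sum (i-j)^2 p$, homogeneity $\sum p/(1+|i-j|)$, correlation
$(\sum ij\,p - \mu_x\mu_y)/(\sigma_x\sigma_y)$, sum average
$\sum_k k\, p_{x+y}(k)$, variance $\sum (i-\mu_x)^2 p$ and dissimilarity
$\sum |i-j|\,p$. Two published "homogeneity" definitions exist; the inverse
difference $1+|i-j|$ denominator is the default and the inverse difference
moment $1+(i-j)^2$ is available as `homogeneity_kind = "idm"`.

**Rotation invariance** (`rotation_invariant_features()`): in 3D the 26
neighbors of a voxel reduce to 13 unique direction pairs; features are
computed per direction and then averaged (features are averaged, not
matrices). The direction set is closed under the 48 signed axis permutations
of the grid, so the average is geometrically invariant. One numerical detail
makes it *bit*-identical rather than merely equal to rounding: the 13
per-direction values are sorted before summation, removing the dependence of
floating-point addition on direction order. Directions with no valid voxel
pair (very thin ROIs) are excluded from the average and counted in the
output's `n_directions`.

`extract_features()` chains crop, resample, quantize, global + second-order
features and the ROI mean PDFF into a single tibble row carrying its full
provenance (gray-level count, bound mode, bin count, directions used).

## The synthetic cohort

`generate_phantom()` builds a sagittal-like volume (default 24 × 24 × 64
voxels at 1 mm isotropic) containing four disjoint ellipsoidal "vertebral
bodies" (labels 1-4 = L1-L4, about 1800 voxels each) along the cranio-caudal
axis. Within each region the PDFF field is a Gaussian random field — white
noise smoothed with a Gaussian kernel of $\sigma$ = `correlation_length`
(default 2 mm) — standardized *exactly* to the requested mean and smooth-field
SD inside the region, plus independent voxel noise (default 1.5%). The smooth
component is scaled to $\sqrt{\text{local\_sd}^2 - \text{noise\_sd}^2}$ so
the realized total SD equals `local_sd`. Exact per-region standardization
(rather than scaling by the field's theoretical SD) was chosen so the
generator's post-conditions — region mean within ±0.5% and SD within ±15% of
target even for ~10³-voxel regions of a spatially correlated field — hold by
construction, not merely in expectation. Values are clipped to [0, 100]%
afterwards; if more than 1% of in-mask voxels clip, a warning notes that the
intensity distribution (notably skewness) is distorted. The two texture knobs
are independent: `correlation_length` sets the spatial scale the GLCM
features see, `local_sd` the amplitude.

`generate_cohort()` arranges phantoms into a 5 age-group × 2 sex design.
The default cell sizes (female 30/9/13/27/27, male 12/15/5/9/9; 156 subjects)
and cell mean PDFFs (female rising 27.2 → 49.3% across age groups, male
rising 32.0 → 42.0% and plateauing) encode the structure such cross-sectional
studies report: marrow fat increases with age (red-to-yellow marrow
conversion), steeper in women around menopause, and the female cells carry a
slightly higher heterogeneity amplitude (`local_sd` 9.0 vs 8.4%). The
per-subject level means add a lumbar gradient (offsets −1.27/−1.07/−0.01/+2.36%
about the subject mean, re-centering a 35.9 → 39.5% L1→L4 gradient) and a
between-subject SD of 7%. Covariates: age uniform within the cell's decade
(60-75 years for the open-ended last group), BMI normal by sex
(26.1 ± 5.2 female, 28.3 ± 4.6 male kg/m², truncated at 15). Subject $i$
uses seed `master_seed * 100000 + i` in cell-major order, so extending a
cohort never reshuffles existing subjects.

What the phantom does *not* emulate: anatomical vertebra shapes, cortical
bone, the basivertebral vein, degenerative endplate changes, or any
literature-matched voxel-level marrow microstructure — no published
within-ROI spatial statistics exist to calibrate against, so phantom realism
is qualitative. Passing tests therefore demonstrate the correctness and
sensitivity of the *measurement chain* (generator → features → statistics),
not quantitative agreement of feature values with any in-vivo cohort; no
attempt is made to reproduce published cohort feature tables numerically.
One known scale caveat: toolboxes that renormalize gray levels report
energy/sum-average/variance on different scales than the standard
definitions used here, so cross-toolbox comparisons need care.

## Group statistics

The statistics stage mirrors the study design it serves, on any feature
table:

* `ks_normality()` — one-sample Kolmogorov-Smirnov distance to a normal with
  the sample mean/SD. Estimating parameters from the same sample makes the
  plain KS p-value anticonservative (this is also what common SPSS defaults
  do); the Lilliefors-corrected variant is available and documented.
* `anova_across_groups()` — classical equal-variance one-way ANOVA computed
  explicitly from the sums of squares
  ($SS_{tot} = SS_{between} + SS_{within}$ is asserted to $10^{-10}$
  relative in tests), with pooled-variance pairwise t tests and Bonferroni
  adjustment $p_{adj} = \min(1, m\,p)$ as post-hoc analysis. A Welch option
  covers heteroscedastic groups. Groups with fewer than 2 observations are
  excluded with a warning.
* `adjusted_sex_comparison()` — the general linear model
  `feature ~ sex + age + bmi`, solved directly by QR on the design matrix;
  reports the sex coefficient with SE and two-sided p-value, plus adjusted
  group means (predictions at pooled covariate means). Rank deficiency is an
  error naming the collinear column. With covariates balanced across sexes
  it reduces exactly to the raw mean difference.
* `average_levels()` — the per-subject L1-L4 average, using available cases
  (subjects missing a level are averaged over the levels present, matching
  how per-level sample sizes vary in real cohorts).

Tests are two-sided at $\alpha$ = 0.05. No multiplicity correction is applied
*across* the 12 features, matching the study design this stage reproduces;
the Bonferroni correction applies to pairwise post-hoc comparisons within a
grouping. Age groups are the decade bins 20-29, …, 50-59, ≥60.

`run_pipeline()` chains cohort → extraction → statistics, writes every
artifact (covariates, long and subject-averaged feature tables, tidy
statistics CSVs, a text report) together with the effective config as YAML,
and is deterministic given the config's seed.

## Numerical and design choices, in brief

* ANOVA and the GLM are computed from first principles (sums of squares, QR)
  and cross-checked in the test suite against `stats::aov()` / `stats::lm()`
  as independent references; `ks.test`, `lillie.test`, `p.adjust`-style
  capping and distribution functions come from base R / nortest.
* The field-map grid step (15 Hz) is small enough that the residual basin of
  the true optimum is always hit for this echo train; refinement then
  converges quadratically. $W = F = 0$ voxels are invalid, not 0/0.
* Sorted direction averaging (above) trades a negligible cost for exact
  permutation invariance.
* Degenerate inputs are contracts, not accidents: constant ROIs yield the
  analytic feature values with correlation flagged undefined; empty
  direction sets, empty masks, all-zero signals, rank-deficient designs and
  non-positive spacings raise informative errors.
* Default problem sizes (24 × 24 × 64 phantoms, ~1800-voxel ROIs, 10-20
  cohort replicates in the calibration studies) were chosen as the smallest
  sizes at which the generator's post-conditions and the statistical power
  of the built-in trends are comfortably realized.

## A small worked example

```{r example, eval = FALSE}
cells <- default_cohort_cells()
cells$n <- c(6L, 3L, 3L, 5L, 5L, 3L, 3L, 2L, 2L, 2L) # scaled-down cohort
res <- run_pipeline(pipeline_config(seed = 7, cells = cells))

dplyr::select(res$level_anova, feature, statistic, p_value)
res$sex_adjusted
plot_feature_by_group(res$subject_features, "pdff_mean", "age_group",
                      facet_sex = TRUE)
```

## Limitations

The phantom's ellipsoidal geometry and stationary Gaussian texture are a
deliberate simplification; effect sizes measured on it do not transfer
quantitatively to in-vivo marrow. The water-fat module simulates phase-correct
data — vendor phase-error correction for bipolar readouts is out of scope, so
equivalence with any scanner's online reconstruction can only be argued by
self-consistency (simulate → fit round trips). T1 bias, field-map spatial
regularization and fat unsaturation analysis are likewise out of scope.
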