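# marrowtex

Quantitative MRI analysis of vertebral bone marrow in R: from multi-echo
chemical-shift-encoded (CSE) gradient-echo signals to proton density fat
fraction (PDFF) maps, from masked PDFF maps to 3D texture features, and from
feature tables to the group statistics of a cross-sectional cohort study.

Bone marrow converts from hematopoietic ("red") to fatty ("yellow") marrow
with age, and PDFF — the fat signal over the sum of fat and water signals,
in percent — measures that conversion absolutely. Beyond the mean fat
fraction, the *spatial heterogeneity* of marrow carries additional
information, and that is what texture analysis quantifies. marrowtex is
aimed at researchers building or validating such pipelines: every stage is a
plain R function on tidy data, and a built-in synthetic cohort generator
makes the whole chain testable without any patient data.

## What it computes

**Water–fat separation.** The complex voxel signal across echo times is
modelled as

```
s(TEn) = (W + cF(TEn) · F) · exp(i·2π·ψ·TEn) · exp(−R2*·TEn)
```

with nonnegative water/fat amplitudes `W, F`, field-map frequency `ψ` and a
single `R2* = 1/T2*`; `cF(t) = Σp αp·exp(i·2π·γ·B0·Δδp·1e-6·t)` is the
multi-peak fat dephasing coefficient (a configurable seven-peak spectrum by
default). `fit_water_fat()` estimates the four parameters by variable
projection (field-map grid search + exact nonnegative amplitude solve)
followed by Levenberg–Marquardt refinement; `PDFF = 100·F/(W+F)`.

**Texture features.** Per vertebra (labels L1–L4 in a mask), after isotropic
resampling and uniform gray-level quantization (100 levels over the absolute
0–100 % PDFF scale by default): three global histogram features (variance,
skewness, excess kurtosis) and eight gray-level co-occurrence matrix (GLCM)
features — energy, entropy (bits), contrast, homogeneity, correlation, sum
average, variance, dissimilarity — computed per offset and averaged over the
13 unique 3D neighbor directions for rotation invariance.

**Group statistics.** Kolmogorov–Smirnov normality screening, one-way ANOVA
(computed from sums of squares) with Bonferroni-adjusted pairwise post-hoc
tests across vertebral levels or age groups, and a covariate-adjusted sex
comparison via the general linear model `feature ~ sex + age + bmi`.

**Synthetic cohort.** `generate_phantom()` / `generate_cohort()` build
four-vertebra PDFF phantoms (Gaussian-random-field texture with controllable
correlation length and amplitude) arranged in a 5 age-group × 2 sex design
with realistic covariates, deterministic under a master seed.

## A worked example

```r
library(marrowtex)
library(dplyr)

cells <- default_cohort_cells()          # 5 age groups x 2 sexes
cells$n <- c(6L, 3L, 3L, 5L, 5L, 3L, 3L, 2L, 2L, 2L)  # scaled-down cohort
res <- run_pipeline(pipeline_config(seed = 7, cells = cells))

summarize_groups(res$features, "pdff_mean", "level")
#>     feature level  n  mean    sd
#> 1 pdff_mean    L1 34 33.90 10.18
#> 2 pdff_mean    L2 34 34.09 10.19
#> 3 pdff_mean    L3 34 35.15 10.20
#> 4 pdff_mean    L4 34 37.51 10.22

filter(res$age_anova, sex == "female", feature == "pdff_mean") |>
  select(sex, feature, statistic, p_value)
#>      sex   feature statistic  p_value
#> 1 female pdff_mean      10.9 0.000147

filter(res$sex_adjusted, feature %in% c("pdff_mean", "contrast")) |>
  select(feature, sex_effect, std_error, p_value)
#>     feature sex_effect std_error  p_value
#> 1  contrast      -3.60      0.75 4.11e-05
#> 2 pdff_mean       4.22      2.51 1.03e-01
```

Reading the output: mean PDFF rises from L1 to L4 (the generator's lumbar
gradient surviving feature extraction); within females, mean PDFF differs
strongly across age groups (F = 10.9 — the age trend); and after adjusting
for age and BMI, GLCM contrast is significantly *lower* in males
(sex effect −3.60, male minus female), reflecting the higher heterogeneity
amplitude built into the female cells, while mean PDFF itself does not
differ by sex. `autoplot()` methods and `plot_feature_by_group()` visualize
each result; `tidy()` / `glance()` return the post-hoc and omnibus tables as
tibbles.

Single stages compose the same way by hand:

```r
acq <- acquisition_params()                       # 8 echoes, 1.4/1.1 ms, 3 T
s   <- simulate_echo_series(voxel_model(W = 0.6, F = 0.4, psi = 20, r2star = 40), acq)
compute_pdff(fit_water_fat(s, acq))               # 40 (to machine precision)

ph  <- generate_phantom(phantom_spec(seed = 1))
extract_features(ph$map, ph$mask, label = 2)      # one tidy feature row
```

Volumes read/write as NIfTI-1 (`load_volume()` / `save_volume()`), feature
and covariate tables as CSV, acquisition metadata as JSON, pipeline configs
as YAML.

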