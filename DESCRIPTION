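Package: marrowtex
Title: Vertebral Bone Marrow Fat-Fraction Mapping and 3D Texture Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative MRI studies of vertebral bone marrow:
    forward simulation and voxelwise fitting of multi-echo chemical-shift-encoded
    gradient-echo signals with a multi-peak fat spectrum and a single T2* to
    produce proton density fat fraction (PDFF) maps; masked 3D texture feature
    extraction (global histogram features and eight gray-level co-occurrence
    matrix features averaged over the 13 unique neighbor directions); a
    synthetic phantom and cohort generator with controllable per-vertebra fat
    gradients and spatial heterogeneity; and the group-statistics stage used in
    cross-sectional marrow studies (Kolmogorov-Smirnov normality screening,
    one-way ANOVA with Bonferroni post-hoc tests, and covariate-adjusted sex
    comparisons via a general linear model). All results are returned as tidy
    tibbles suitable for piping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    nortest,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Config/testthat/parallel: false
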