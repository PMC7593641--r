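#' Default cohort design: 5 age groups x 2 sexes
#'
#' One row per (sex, age-group) cell with the cell size, the cell's mean
#' L1--L4 PDFF in percent and its within-vertebra heterogeneity amplitude
#' (`local_sd`). The defaults encode the structure a cross-sectional marrow
#' study expects: PDFF rising with age in both sexes (steeper and higher in
#' older women, plateauing in older men), and a larger heterogeneity
#' amplitude in the female cells. Cell sizes follow a 156-subject design
#' (female 30/9/13/27/27, male 12/15/5/9/9 across age groups 20--29, 30--39,
#' 40--49, 50--59, >= 60).
#'
#' @return A tibble with columns `sex`, `age_group`, `n`, `pdff_mean`,
#'   `local_sd`.
#' @export
default_cohort_cells <- function() {
  tibble::tibble(
    sex = rep(c("female", "male"), each = 5),
    age_group = rep(1:5, 2),
    n = c(30L, 9L, 13L, 27L, 27L, 12L, 15L, 5L, 9L, 9L),
    pdff_mean = c(
      27.19, 27.27, 34.55, 40.51, 49.34, # female, rising with age
      31.97, 35.28, 38.20, 42.04, 41.83  # male, plateauing in group 5
    ),
    local_sd = c(rep(9.0, 5), rep(8.4, 5))
  )
}

#' Specification of a synthetic study cohort
#'
#' @param cells Tibble describing the (sex, age-group) design; see
#'   [default_cohort_cells()]. Required columns: `sex`, `age_group`, `n`;
#'   optional per-cell overrides: `pdff_mean`, `local_sd`,
#'   `correlation_length`, `noise_sd`.
#' @param level_offsets Per-vertebra PDFF offsets in percent added to each
#'   subject's mean to create the L1 -> L4 gradient. The default re-centers
#'   the lumbar gradient 35.89/36.09/37.15/39.52 observed across a healthy
#'   adult cohort.
#' @param subject_sd Between-subject SD of mean PDFF within a cell (percent).
#' @param age_ranges List of length-2 age bounds per age group (years).
#' @param bmi_mean,bmi_sd Named vectors (`female`, `male`) for the BMI draw
#'   (kg/m^2, normal truncated at 15).
#' @param grid_shape,voxel_spacing,correlation_length,noise_sd Phantom
#'   parameters shared by all cells unless overridden per cell.
#' @param seed Master integer seed. Subject `i` (in cell-major order) uses
#'   seed `seed * 100000 + i`, so extending a cohort never reshuffles
#'   existing subjects.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(cells = default_cohort_cells(),
                        level_offsets = c(-1.27, -1.07, -0.01, 2.36),
                        subject_sd = 7,
                        age_ranges = list(c(20, 29), c(30, 39), c(40, 49), c(50, 59), c(60, 75)),
                        bmi_mean = c(female = 26.1, male = 28.3),
                        bmi_sd = c(female = 5.2, male = 4.6),
                        grid_shape = c(24L, 24L, 64L),
                        voxel_spacing = c(1, 1, 1),
                        correlation_length = 2,
                        noise_sd = 1.5,
                        seed = 1L) {
  if (!is.data.frame(cells) || !all(c("sex", "age_group", "n") %in% names(cells))) {
    abort("`cells` needs columns `sex`, `age_group`, `n`.")
  }
  if (!all(cells$sex %in% c("female", "male"))) {
    abort("`cells$sex` must be 'female' or 'male'.")
  }
  if (!all(cells$age_group %in% seq_along(age_ranges))) {
    abort("`cells$age_group` must index into `age_ranges`.")
  }
  if (any(cells$n < 0) || sum(cells$n) == 0) {
    abort("Cohort is empty: at least one cell must have n > 0.")
  }
  if (abs(seed) > 20000) abort("`seed` must be a small integer (|seed| <= 20000).")
  structure(
    list(
      cells = tibble::as_tibble(cells), level_offsets = level_offsets,
      subject_sd = subject_sd, age_ranges = age_ranges,
      bmi_mean = bmi_mean, bmi_sd = bmi_sd,
      grid_shape = grid_shape, voxel_spacing = voxel_spacing,
      correlation_length = correlation_length, noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort of PDFF phantoms with covariates
#'
#' Draws one subject per row of the design's cell counts: covariates (age
#' uniform within the cell's age range, BMI normal by sex, truncated at 15),
#' a subject-level mean PDFF (cell mean + between-subject deviation), and a
#' four-vertebra phantom realizing that subject's per-level means and the
#' cell's heterogeneity amplitude. Deterministic: the same spec always
#' produces byte-identical covariates and volumes.
#'
#' @param spec A [cohort_spec()].
#' @param keep_volumes If `FALSE`, drop the map/mask arrays from the records
#'   (covariates only).
#' @return A list with `subjects` (list of records: `id`, `sex`, `age_group`,
#'   `age`, `bmi`, `map`, `mask`, `phantom_spec`) and `covariates` (tibble
#'   `id`, `sex`, `age`, `bmi`, plus `age_group`).
#' @export
generate_cohort <- function(spec, keep_volumes = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  cells <- spec$cells
  cell_val <- function(cell, name, default) {
    if (name %in% names(cell)) cell[[name]] else default
  }
  subjects <- list()
  counter <- 0L
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    if (cell$n == 0) next
    rng <- spec$age_ranges[[cell$age_group]]
    for (k in seq_len(cell$n)) {
      counter <- counter + 1L
      sseed <- spec$seed * 100000L + counter
      set.seed(sseed)
      age <- round(runif(1, rng[1], rng[2]))
      bmi <- max(rnorm(1, spec$bmi_mean[[cell$sex]], spec$bmi_sd[[cell$sex]]), 15)
      subj_mean <- cell_val(cell, "pdff_mean", 37) + rnorm(1, 0, spec$subject_sd)
      lv <- pmin(pmax(subj_mean + spec$level_offsets, 0.5), 99.5)
      pspec <- phantom_spec(
        grid_shape = spec$grid_shape,
        voxel_spacing = spec$voxel_spacing,
        level_means = lv,
        local_sd = cell_val(cell, "local_sd", 9),
        correlation_length = cell_val(cell, "correlation_length", spec$correlation_length),
        noise_sd = cell_val(cell, "noise_sd", spec$noise_sd),
        seed = sseed
      )
      rec <- list(
        id = sprintf("S%03d", counter),
        sex = cell$sex, age_group = cell$age_group,
        age = age, bmi = bmi, phantom_spec = pspec
      )
      if (keep_volumes) {
        ph <- generate_phantom(pspec)
        rec$map <- ph$map
        rec$mask <- ph$mask
      }
      subjects[[counter]] <- rec
    }
  }
  covariates <- purrr::map_dfr(subjects, function(s) {
    tibble::tibble(
      id = s$id, sex = s$sex, age = s$age, bmi = s$bmi, age_group = s$age_group
    )
  })
  list(subjects = subjects, covariates = covariates)
}
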