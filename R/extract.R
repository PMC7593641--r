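#' Default feature-extraction configuration
#'
#' @param ng Number of gray levels for quantization.
#' @param bounds_mode `"fixed"` (absolute 0--100% PDFF scale, default) or
#'   `"roi_minmax"`.
#' @param bounds Quantization bounds when `bounds_mode = "fixed"`.
#' @param target_spacing_mm Isotropic resampling target in mm; `NULL` skips
#'   resampling (volumes already isotropic are passed through unchanged
#'   anyway).
#' @param interpolation Interpolator for the intensity map (masks always use
#'   nearest-neighbor).
#' @param homogeneity_kind Homogeneity variant, see [glcm_features()].
#' @param global_method Moment computation for the global features, see
#'   [global_features()].
#' @return Named list of configuration values.
#' @export
extract_config <- function(ng = 100L,
                           bounds_mode = c("fixed", "roi_minmax"),
                           bounds = c(0, 100),
                           target_spacing_mm = 1,
                           interpolation = "linear",
                           homogeneity_kind = "inverse_difference",
                           global_method = "binned") {
  list(
    ng = as.integer(ng), bounds_mode = match.arg(bounds_mode), bounds = bounds,
    target_spacing_mm = target_spacing_mm, interpolation = interpolation,
    homogeneity_kind = homogeneity_kind, global_method = global_method
  )
}

#' Names of the 12 per-ROI features
#' @return Character vector in canonical output order.
#' @export
feature_names <- function() {
  c(
    "variance_global", "skewness_global", "kurtosis_global",
    "energy", "entropy", "contrast", "homogeneity", "correlation",
    "sum_average", "variance_glcm", "dissimilarity", "pdff_mean"
  )
}

#' Extract all texture features for one labeled ROI
#'
#' Runs the full per-ROI chain on a PDFF map and its label mask: crop to the
#' label's bounding box, resample map (configured interpolator) and mask
#' (nearest-neighbor) to isotropic voxels, quantize gray levels, then compute
#' the three global histogram features, the eight direction-averaged GLCM
#' features and the ROI mean PDFF.
#'
#' @param map 3D PDFF array in percent (attribute `spacing`, or pass
#'   `spacing`).
#' @param mask 3D label array of the same shape.
#' @param label Integer label to extract (must be present in `mask`).
#' @param config See [extract_config()].
#' @param spacing Voxel spacing override (mm).
#' @return One-row tibble: `label`, `n_voxels`, the 12 features in
#'   [feature_names()] order, and provenance columns `ng`, `bounds_mode`,
#'   `n_bins_global`, `n_directions`.
#' @export
extract_features <- function(map, mask, label, config = extract_config(),
                             spacing = attr(map, "spacing")) {
  if (!identical(dim(map), dim(mask))) abort("`map` and `mask` shapes differ.")
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  if (!any(mask == label)) abort(sprintf("Label %s not present in mask.", label))

  # crop to bounding box (with a 1-voxel margin for interpolation support)
  idx <- which(mask == label, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + 1L, dim(mask))
  sub_map <- map[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub_mask <- (mask == label)[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  storage.mode(sub_mask) <- "integer"

  if (!is.null(config$target_spacing_mm)) {
    sub_map <- resample_isotropic(
      sub_map, spacing, config$target_spacing_mm,
      interpolation = config$interpolation
    )
    sub_mask <- resample_isotropic(
      sub_mask, spacing, config$target_spacing_mm,
      interpolation = "nearest"
    )
  }

  vals <- sub_map[sub_mask > 0]
  glob <- global_features(vals, method = config$global_method)

  q <- quantize_gray_levels(
    sub_map, sub_mask,
    ng = config$ng, bounds_mode = config$bounds_mode, bounds = config$bounds
  )
  so <- rotation_invariant_features(
    q, homogeneity_kind = config$homogeneity_kind
  )

  tibble::tibble(
    label = as.integer(label),
    n_voxels = glob$n_voxels,
    variance_global = glob$variance_global,
    skewness_global = glob$skewness_global,
    kurtosis_global = glob$kurtosis_global,
    energy = so$energy, entropy = so$entropy, contrast = so$contrast,
    homogeneity = so$homogeneity, correlation = so$correlation,
    sum_average = so$sum_average, variance_glcm = so$variance_glcm,
    dissimilarity = so$dissimilarity,
    pdff_mean = mean(vals),
    ng = config$ng,
    bounds_mode = config$bounds_mode,
    n_bins_global = glob$n_bins,
    n_directions = attr(so, "n_directions")
  )
}

#' Extract the feature table of a whole cohort
#'
#' Applies [extract_features()] to every (subject, vertebral level) pair of a
#' generated cohort and binds covariates, producing the long feature table
#' the statistics stage consumes.
#'
#' @param cohort Result of [generate_cohort()] (volumes kept).
#' @param config See [extract_config()].
#' @param labels Vertebra labels to extract (default 1:4 = L1..L4).
#' @return Tibble, one row per (subject, level): `id`, `sex`, `age`,
#'   `age_group`, `bmi`, `level` (`"L1"`..`"L4"`), features and provenance.
#' @export
extract_cohort_features <- function(cohort, config = extract_config(),
                                    labels = 1:4) {
  purrr::map_dfr(cohort$subjects, function(s) {
    if (is.null(s$map)) abort("Cohort was generated with `keep_volumes = FALSE`.")
    purrr::map_dfr(labels, function(lab) {
      row <- extract_features(s$map, s$mask, lab, config = config)
      dplyr::bind_cols(
        tibble::tibble(
          id = s$id, sex = s$sex, age = s$age,
          age_group = s$age_group, bmi = s$bmi,
          level = paste0("L", lab)
        ),
        row
      )
    })
  })
}
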