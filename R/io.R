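#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return Numeric or integer 3D array with attributes `spacing` (mm, from
#'   the header pixdim) and `affine` (4x4 voxel-to-world matrix).
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)
  if (any(spacing <= 0)) abort("Non-positive voxel spacing in NIfTI header.")
  arr <- as.array(img)
  if (length(dim(arr)) != 3) abort("Expected a 3D volume.")
  attr(arr, "spacing") <- spacing[1:3]
  attr(arr, "affine") <- structure(RNifti::xform(img), class = NULL)
  arr
}

#' Write a 3D volume as NIfTI-1
#'
#' Intensity maps are written as float32, integer/label arrays as uint8.
#'
#' @param volume 3D array; attribute `spacing` (mm) is honored.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Voxel spacing override (mm, length 3).
#' @return `path`, invisibly.
#' @export
save_volume <- function(volume, path, spacing = attr(volume, "spacing")) {
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  datatype <- if (is.integer(volume)) "uint8" else "float"
  img <- RNifti::asNifti(array(volume, dim(volume)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

FEATURE_TABLE_SCHEMA <- "marrowtex feature table v1"

#' Write a feature table as CSV
#'
#' Fixed column order (covariates first, then the 12 features, then
#' provenance), UTF-8, a schema-version comment line on top, and undefined
#' values as empty cells.
#'
#' @param rows Feature table (tibble).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0) abort("`rows` must be a nonempty data frame.")
  lead <- intersect(
    c("id", "sex", "age", "age_group", "bmi", "level", "label", "n_voxels"),
    names(rows)
  )
  feats <- intersect(feature_names(), names(rows))
  rest <- setdiff(names(rows), c(lead, feats))
  rows <- rows[, c(lead, feats, rest)]
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", FEATURE_TABLE_SCHEMA), con)
  utils::write.csv(rows, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Write a subject covariate table (`id,sex,age,bmi`)
#'
#' @param covariates Tibble with at least `id`, `sex`, `age`, `bmi`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(covariates, path) {
  need <- c("id", "sex", "age", "bmi")
  miss <- setdiff(need, names(covariates))
  if (length(miss) > 0) abort(paste("Missing columns:", paste(miss, collapse = ", ")))
  readr::write_csv(covariates[, c(need, setdiff(names(covariates), need))], path)
  invisible(path)
}

#' Read a subject covariate table
#'
#' @param path CSV path with header `id,sex,age,bmi`.
#' @return Tibble.
#' @export
read_covariates <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write acquisition parameters as a JSON sidecar
#'
#' @param acq An [acquisition_params()] object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_acquisition_json <- function(acq, path) {
  x <- unclass(acq)
  x$fat_peaks <- as.data.frame(x$fat_peaks)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an acquisition JSON sidecar
#'
#' @param path JSON path written by [write_acquisition_json()].
#' @return An [acquisition_params()] object.
#' @export
read_acquisition_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  acquisition_params(
    n_echoes = x$n_echoes, te1 = x$te1, delta_te = x$delta_te,
    tr = x$tr, flip_angle = x$flip_angle, field_strength = x$field_strength,
    fat_peaks = tibble::as_tibble(x$fat_peaks)
  )
}
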