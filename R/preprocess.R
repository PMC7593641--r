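#' Resample a 3D volume to isotropic voxels
#'
#' Regridding onto an isotropic lattice aligned with the first voxel center
#' (output voxel `i` samples input index `1 + (i - 1) * target / spacing`).
#' Intensity maps use trilinear interpolation by default; label masks must be
#' resampled with `"nearest"` so labels stay integral.
#'
#' @param volume 3D numeric array.
#' @param spacing Input voxel spacing in mm (length 3); taken from
#'   `attr(volume, "spacing")` if missing.
#' @param target_spacing Desired isotropic voxel size in mm (scalar > 0).
#' @param interpolation `"linear"` (trilinear) or `"nearest"`.
#' @return Resampled 3D array with attribute `spacing = rep(target_spacing, 3)`.
#' @export
resample_isotropic <- function(volume, spacing = attr(volume, "spacing"),
                               target_spacing = 1,
                               interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (is.null(spacing)) abort("`spacing` is required (none attached to `volume`).")
  if (length(spacing) != 3 || any(spacing <= 0)) abort("`spacing` must be 3 positive values.")
  if (length(target_spacing) != 1 || target_spacing <= 0) {
    abort("`target_spacing` must be a positive scalar.")
  }
  dm <- dim(volume)
  if (length(dm) != 3) abort("`volume` must be a 3D array.")

  if (all(abs(spacing - target_spacing) < 1e-12)) {
    out <- volume
    attr(out, "spacing") <- rep(target_spacing, 3)
    return(out)
  }

  n_out <- pmax(floor((dm - 1) * spacing / target_spacing) + 1, 1)
  coords <- lapply(1:3, function(ax) {
    1 + (seq_len(n_out[ax]) - 1) * target_spacing / spacing[ax]
  })

  if (interpolation == "nearest") {
    idx <- lapply(1:3, function(ax) pmin(pmax(round(coords[[ax]]), 1), dm[ax]))
    out <- volume[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  } else {
    lo <- lapply(1:3, function(ax) pmin(pmax(floor(coords[[ax]]), 1), dm[ax]))
    hi <- lapply(1:3, function(ax) pmin(lo[[ax]] + 1, dm[ax]))
    fr <- lapply(1:3, function(ax) coords[[ax]] - lo[[ax]])
    out <- array(0, n_out)
    for (b in 0:7) {
      bx <- bitwAnd(b, 1L) > 0; by <- bitwAnd(b, 2L) > 0; bz <- bitwAnd(b, 4L) > 0
      ix <- if (bx) hi[[1]] else lo[[1]]
      iy <- if (by) hi[[2]] else lo[[2]]
      iz <- if (bz) hi[[3]] else lo[[3]]
      wx <- if (bx) fr[[1]] else 1 - fr[[1]]
      wy <- if (by) fr[[2]] else 1 - fr[[2]]
      wz <- if (bz) fr[[3]] else 1 - fr[[3]]
      w <- outer(outer(wx, wy), wz)
      out <- out + w * volume[ix, iy, iz, drop = FALSE]
    }
  }
  attr(out, "spacing") <- rep(target_spacing, 3)
  out
}

#' Choose a histogram bin count by combining classical rules
#'
#' Evaluates the Sturges (`ceiling(log2(n)) + 1`), Scott
#' (`range / (3.49 * sd * n^(-1/3))`) and Freedman--Diaconis
#' (`range / (2 * IQR * n^(-1/3))`) rules and returns their maximum — the
#' most conservative combination against histogram sparseness. The
#' Freedman--Diaconis rule is skipped when the IQR is zero.
#'
#' @param values Numeric vector (>= 2 finite values with nonzero range).
#' @return Integer bin count (>= 2), with attribute `rules` giving the three
#'   individual counts.
#' @export
#' @examples
#' choose_histogram_bins(rnorm(1000))
choose_histogram_bins <- function(values) {
  v <- values[is.finite(values)]
  n <- length(v)
  if (n < 2) abort("Need at least 2 finite values.")
  rng <- diff(range(v))
  if (rng == 0) abort("Values are constant: histogram range is zero.")
  sturges <- ceiling(log2(n)) + 1
  scott_h <- 3.49 * sd(v) * n^(-1 / 3)
  scott <- if (scott_h > 0) ceiling(rng / scott_h) else NA_integer_
  iqr <- stats::IQR(v)
  fd <- if (iqr > 0) ceiling(rng / (2 * iqr * n^(-1 / 3))) else NA_integer_
  rules <- c(sturges = sturges, scott = scott, fd = fd)
  out <- max(2L, max(rules, na.rm = TRUE))
  attr(out, "rules") <- rules
  out
}

#' Quantize gray levels onto 1..Ng with equally sized bins
#'
#' Uniform gray-level quantization of an intensity volume inside a mask:
#' `Ng` equally sized bins between `bounds[1]` and `bounds[2]`, with the
#' lower bound mapping to level 1 and the upper bound to level `Ng`
#' (`level = min(Ng, floor((v - lo) / ((hi - lo) / Ng)) + 1)`, clamped to
#' `[1, Ng]`). Voxels outside the mask are 0. With `bounds_mode =
#' "roi_minmax"` the bounds are the in-mask minimum and maximum (the
#' "gray levels present"); the default fixed `(0, 100)` uses the absolute
#' PDFF scale. A zero-range ROI maps every voxel to level 1.
#'
#' @param map 3D numeric array (PDFF in percent).
#' @param mask 3D logical/integer array of the same shape; voxels with
#'   `mask > 0` are quantized.
#' @param ng Number of gray levels (default 100).
#' @param bounds_mode `"fixed"` or `"roi_minmax"`.
#' @param bounds Length-2 numeric bounds used when `bounds_mode = "fixed"`.
#' @return Integer 3D array of levels in `1..ng` inside the mask (0 outside),
#'   with attributes `ng`, `bounds`, `bounds_mode`.
#' @export
quantize_gray_levels <- function(map, mask, ng = 100L,
                                 bounds_mode = c("fixed", "roi_minmax"),
                                 bounds = c(0, 100)) {
  bounds_mode <- match.arg(bounds_mode)
  if (!identical(dim(map), dim(mask))) abort("`map` and `mask` shapes differ.")
  if (ng < 2) abort("`ng` must be >= 2.")
  sel <- mask > 0
  if (!any(sel)) abort("`mask` is empty.")
  v <- map[sel]
  if (bounds_mode == "roi_minmax") bounds <- range(v)
  lo <- bounds[1]; hi <- bounds[2]
  if (bounds_mode == "fixed" && hi <= lo) abort("Upper bound must exceed lower bound.")
  q <- array(0L, dim(map))
  if (hi > lo) {
    w <- (hi - lo) / ng
    lev <- floor((v - lo) / w) + 1
    q[sel] <- as.integer(pmin(pmax(lev, 1), ng))
  } else {
    q[sel] <- 1L # degenerate (constant) ROI
  }
  attr(q, "ng") <- as.integer(ng)
  attr(q, "bounds") <- c(lo, hi)
  attr(q, "bounds_mode") <- bounds_mode
  q
}
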