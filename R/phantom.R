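# Separable 3D Gaussian smoothing with edge renormalization (kernel weights
# inside the volume are rescaled to sum to 1 at each voxel).
gaussian_smooth_3d <- function(x, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-r:r) / s)^2)
    x <- convolve_axis(x, k, ax)
  }
  x
}

# 1D convolution of a 3D array along axis `ax` with kernel `k`, normalizing
# by the in-bounds kernel mass so constants are preserved at the edges.
convolve_axis <- function(x, k, ax) {
  dm <- dim(x)
  n <- dm[ax]
  r <- (length(k) - 1L) / 2L
  perm <- c(ax, setdiff(1:3, ax))
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = n)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  wsum <- numeric(n)
  for (j in seq_along(k)) {
    off <- j - r - 1L # source row offset
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + k[j] * m[src[ok], , drop = FALSE]
    wsum[ok] <- wsum[ok] + k[j]
  }
  out <- out / wsum
  xp <- array(out, dm[perm])
  aperm(xp, order(perm))
}

#' Specification of a four-vertebra PDFF phantom
#'
#' Describes a synthetic sagittal-like volume containing four disjoint
#' ellipsoidal "vertebral bodies" (labels 1..4 = L1..L4) stacked along the
#' third (cranio-caudal) axis. Within each region the fat-fraction field is a
#' Gaussian random field (white noise smoothed with kernel sigma =
#' `correlation_length`) standardized exactly to the requested mean and
#' standard deviation, plus independent voxel noise; the two knobs (spatial
#' scale and amplitude) control the texture contrast downstream features see.
#'
#' @param grid_shape Integer vector of 3 voxel counts.
#' @param voxel_spacing Numeric vector of 3 voxel sizes in mm.
#' @param level_means Mean PDFF in percent for L1..L4 (each in `[0, 100]`).
#' @param local_sd Target within-region PDFF standard deviation in percent.
#' @param correlation_length Spatial texture scale in mm (Gaussian kernel
#'   sigma); 0 gives pure white noise.
#' @param noise_sd Independent additive noise SD in percent; must not exceed
#'   `local_sd` (the smooth component is scaled so the total SD is
#'   `local_sd`).
#' @param semi_axes Ellipsoid semi-axes in voxels (length 3); by default sized
#'   from the grid so each region has roughly 1800 voxels.
#' @param seed Integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(24L, 24L, 64L),
                         voxel_spacing = c(1, 1, 1),
                         level_means = c(35.89, 36.09, 37.15, 39.52),
                         local_sd = 9,
                         correlation_length = 2,
                         noise_sd = 1.5,
                         semi_axes = NULL,
                         seed = 1L) {
  if (length(grid_shape) != 3 || any(grid_shape < 8)) {
    abort("`grid_shape` must be 3 integers, each >= 8.")
  }
  if (length(voxel_spacing) != 3 || any(voxel_spacing <= 0)) {
    abort("`voxel_spacing` must be 3 positive values (mm).")
  }
  if (length(level_means) != 4 || any(level_means < 0 | level_means > 100)) {
    abort("`level_means` must be 4 PDFF values in [0, 100].")
  }
  if (local_sd < 0 || noise_sd < 0 || correlation_length < 0) {
    abort("`local_sd`, `noise_sd` and `correlation_length` must be nonnegative.")
  }
  if (noise_sd > local_sd) {
    abort("`noise_sd` must not exceed `local_sd` (total within-region SD).")
  }
  if (is.null(semi_axes)) {
    semi_axes <- c(
      (grid_shape[1] - 7) / 2, (grid_shape[2] - 7) / 2,
      max((grid_shape[3] / 4 - 4) / 2, 2)
    )
  }
  structure(
    list(
      grid_shape = as.integer(grid_shape), voxel_spacing = voxel_spacing,
      level_means = level_means, local_sd = local_sd,
      correlation_length = correlation_length, noise_sd = noise_sd,
      semi_axes = semi_axes, seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

#' Generate a PDFF phantom and its vertebra label mask
#'
#' Realizes the volume described by a [phantom_spec()]: four ellipsoidal
#' regions labeled 1..4 (L1..L4) along the cranio-caudal axis, each filled
#' with a smoothed Gaussian random field standardized within the region to
#' the requested mean and SD, plus independent noise. The smooth component is
#' scaled to `sqrt(local_sd^2 - noise_sd^2)` so the realized total SD matches
#' `local_sd`. Values are clipped to `[0, 100]` at the end; a warning is
#' issued if more than 1% of in-mask voxels clip (heavy clipping distorts the
#' intensity distribution, notably its skewness).
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `map` (3D numeric array, PDFF in percent,
#'   background 0, attribute `spacing`) and `mask` (3D integer array, labels
#'   0..4, same `spacing`).
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(local_sd = 0, noise_sd = 0))
#' unique(ph$map[ph$mask == 1])  # constant at the L1 mean
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_shape
  mask <- array(0L, dm)
  ax <- spec$semi_axes
  cx <- (dm[1] + 1) / 2
  cy <- (dm[2] + 1) / 2
  zc <- (dm[3] / 4) * (seq_len(4) - 0.5) + 0.5
  xs <- seq_len(dm[1]); ys <- seq_len(dm[2]); zs <- seq_len(dm[3])
  for (lab in 1:4) {
    d2 <- outer(
      outer(((xs - cx) / ax[1])^2, ((ys - cy) / ax[2])^2, `+`),
      ((zs - zc[lab]) / ax[3])^2, `+`
    )
    inside <- d2 <= 1
    if (any(mask[inside] != 0)) abort("Vertebra regions overlap; enlarge the grid.")
    idx <- which(inside, arr.ind = TRUE)
    if (any(idx == 1) || any(t(idx) == dm)) {
      abort("A vertebra region touches the volume border; enlarge the grid.")
    }
    mask[inside] <- lab
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)

  map <- array(0, dm)
  smooth_sd <- sqrt(max(spec$local_sd^2 - spec$noise_sd^2, 0))
  field <- if (smooth_sd > 0) {
    gaussian_smooth_3d(array(rnorm(prod(dm)), dm), spec$correlation_length / spec$voxel_spacing)
  } else {
    array(0, dm)
  }
  noise <- if (spec$noise_sd > 0) array(rnorm(prod(dm), 0, spec$noise_sd), dm) else NULL
  for (lab in 1:4) {
    sel <- mask == lab
    v <- numeric(sum(sel))
    if (smooth_sd > 0) {
      f <- field[sel]
      fsd <- sd(f)
      if (fsd > 0) v <- (f - mean(f)) / fsd * smooth_sd
    }
    if (!is.null(noise)) v <- v + noise[sel]
    map[sel] <- spec$level_means[lab] + v - if (!is.null(noise)) mean(noise[sel]) else 0
  }

  inm <- mask > 0
  n_clip <- sum(map[inm] < 0 | map[inm] > 100)
  if (n_clip > 0.01 * sum(inm)) {
    warn(sprintf(
      "%.1f%% of in-mask voxels clipped to [0, 100]; the intensity distribution is distorted.",
      100 * n_clip / sum(inm)
    ))
  }
  map[inm] <- pmin(pmax(map[inm], 0), 100)

  attr(map, "spacing") <- spec$voxel_spacing
  attr(mask, "spacing") <- spec$voxel_spacing
  list(map = map, mask = mask)
}
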