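#' The 13 unique 3D neighbor directions
#'
#' Displacement vectors covering the 26-connected neighborhood of a voxel up
#' to sign: one representative per +/- pair, so co-occurrences accumulated
#' symmetrically over these 13 offsets account for all 26 neighbors.
#' Geometric lengths are 1, sqrt(2) or sqrt(3) voxel units; after isotropic
#' resampling these are physical lengths too. The set is closed (up to sign)
#' under the 48 signed axis permutations, which is what makes
#' direction-averaged features rotation invariant.
#'
#' @return Integer matrix 13 x 3 (columns `dx`, `dy`, `dz`).
#' @export
glcm_offsets <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  # keep one of each +/- pair: first nonzero component (z, then y, then x) positive
  keep <- g[, 3] > 0 |
    (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  out <- g[keep, , drop = FALSE]
  rownames(out) <- NULL
  storage.mode(out) <- "integer"
  out
}

#' Build a masked 3D gray-level co-occurrence matrix for one offset
#'
#' Counts pairs of gray levels at voxel positions `(v, v + d)` where both
#' voxels lie inside the mask (level > 0), accumulating symmetrically (each
#' pair in both orders) and normalizing by the total pair count, giving the
#' joint probability `p(i, j)` of two adjacent voxel intensities. Symmetric
#' accumulation makes the marginals equal (`mu_x = mu_y`, `sigma_x =
#' sigma_y`), which keeps the correlation feature well defined.
#'
#' @param q Quantized volume from [quantize_gray_levels()] (0 outside mask).
#' @param offset Integer displacement `(dx, dy, dz)`.
#' @param ng Number of gray levels; default from `attr(q, "ng")`.
#' @return An object of class `glcm`: list with `p` (ng x ng probability
#'   matrix), `counts` (symmetric integer counts), `n_pairs` (ordered pair
#'   count, i.e. `sum(counts)`), `offset`, `ng`; or `NULL` if the offset
#'   yields no valid pair (flagged-missing direction).
#' @export
build_glcm <- function(q, offset, ng = attr(q, "ng")) {
  if (is.null(ng)) abort("`ng` is required (none attached to `q`).")
  dm <- dim(q)
  if (length(dm) != 3) abort("`q` must be a 3D array.")
  offset <- as.integer(offset)
  if (length(offset) != 3 || all(offset == 0) || any(abs(offset) > 1)) {
    abort("`offset` must be a nonzero displacement with components in {-1, 0, 1}.")
  }
  # index windows such that both v and v + d stay in bounds
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    d <- offset[ax]
    if (dm[ax] + min(0, d) < max(1, 1 + d)) return(NULL) # axis too thin
    src[[ax]] <- seq_len(dm[ax] - abs(d)) + max(0, -d)
    dst[[ax]] <- src[[ax]] + d
  }
  a <- q[src[[1]], src[[2]], src[[3]], drop = FALSE]
  b <- q[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
  ok <- a > 0 & b > 0
  if (!any(ok)) return(NULL)
  i <- a[ok]; j <- b[ok]
  counts <- matrix(
    tabulate((i - 1L) * ng + j, nbins = ng * ng) +
      tabulate((j - 1L) * ng + i, nbins = ng * ng),
    ng, ng, byrow = TRUE
  )
  n_pairs <- sum(counts)
  structure(
    list(
      p = counts / n_pairs, counts = counts, n_pairs = n_pairs,
      offset = offset, ng = as.integer(ng)
    ),
    class = "glcm"
  )
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf(
    "<glcm> Ng = %d, offset (%d, %d, %d), %d ordered pairs\n",
    x$ng, x$offset[1], x$offset[2], x$offset[3], x$n_pairs
  ))
  invisible(x)
}

#' Second-order texture features of one co-occurrence matrix
#'
#' Haralick-style features of a normalized GLCM `p(i, j)`:
#' \itemize{
#'   \item energy (angular second moment): `sum p^2`
#'   \item entropy: `-sum p * log2 p` (bits; `0 * log 0 = 0`)
#'   \item contrast: `sum (i - j)^2 * p`
#'   \item homogeneity (inverse difference): `sum p / (1 + |i - j|)`; set
#'     `homogeneity_kind = "idm"` for the inverse difference moment
#'     `sum p / (1 + (i - j)^2)`
#'   \item correlation: `(sum i*j*p - mu_x*mu_y) / (sigma_x * sigma_y)`,
#'     undefined (`NA`) when either marginal SD is zero
#'   \item sum average: `sum_k k * p_{x+y}(k)`, `k = 2..2*Ng`
#'   \item variance (sum of squares): `sum (i - mu_x)^2 * p`
#'   \item dissimilarity: `sum |i - j| * p`
#' }
#'
#' @param glcm A [build_glcm()] result.
#' @param homogeneity_kind `"inverse_difference"` (default) or `"idm"`.
#' @param entropy_base Logarithm base for entropy (default 2, bits).
#' @return One-row tibble with columns `energy`, `entropy`, `contrast`,
#'   `homogeneity`, `correlation`, `sum_average`, `variance_glcm`,
#'   `dissimilarity`.
#' @export
glcm_features <- function(glcm,
                          homogeneity_kind = c("inverse_difference", "idm"),
                          entropy_base = 2) {
  homogeneity_kind <- match.arg(homogeneity_kind)
  v <- glcm_features_vec(glcm$p, glcm$ng, homogeneity_kind, entropy_base)
  tibble::as_tibble(as.list(v))
}

# cache of level-index matrices keyed by ng (i - j and i + j grids)
.glcm_grid_cache <- new.env(parent = emptyenv())

glcm_grids <- function(ng) {
  key <- as.character(ng)
  g <- .glcm_grid_cache[[key]]
  if (is.null(g)) {
    i <- matrix(seq_len(ng), ng, ng) # row level
    j <- t(i)                        # column level
    g <- list(i = i, j = j, dij = i - j, adij = abs(i - j), sij = i + j)
    .glcm_grid_cache[[key]] <- g
  }
  g
}

# numeric kernel shared by glcm_features() and rotation_invariant_features()
glcm_features_vec <- function(p, ng, homogeneity_kind = "inverse_difference",
                              entropy_base = 2) {
  if (abs(sum(p) - 1) > 1e-8) abort("GLCM is not normalized.")
  gr <- glcm_grids(ng)
  px <- rowSums(p)
  lv <- seq_len(ng)
  mu_x <- sum(lv * px)
  var_x <- sum((lv - mu_x)^2 * px)
  # symmetric accumulation => identical y marginal
  energy <- sum(p^2)
  nz <- p > 0
  pnz <- p[nz]
  entropy <- -sum(pnz * log(pnz)) / log(entropy_base)
  contrast <- sum(gr$dij^2 * p)
  dissimilarity <- sum(gr$adij * p)
  homogeneity <- if (homogeneity_kind == "inverse_difference") {
    sum(p / (1 + gr$adij))
  } else {
    sum(p / (1 + gr$dij^2))
  }
  correlation <- if (var_x > 0) {
    (sum(gr$i * gr$j * p) - mu_x^2) / var_x
  } else {
    NA_real_
  }
  # sum average over the diagonal sum distribution p_{x+y}:
  # sum_k k * p_{x+y}(k) = sum_ij (i + j) * p(i, j)
  sum_average <- sum(gr$sij * p)
  variance_glcm <- sum((gr$i - mu_x)^2 * p)
  c(
    energy = energy, entropy = entropy, contrast = contrast,
    homogeneity = homogeneity, correlation = correlation,
    sum_average = sum_average, variance_glcm = variance_glcm,
    dissimilarity = dissimilarity
  )
}

#' Rotation-invariant second-order features
#'
#' Computes the eight GLCM features separately for each of the 13 unique
#' neighbor directions and averages the per-direction feature values (the
#' features are averaged, not the matrices). Averaging over the full
#' direction set makes the result invariant under the 48 signed axis
#' permutations of the volume; internally the 13 values are sorted before
#' summation so the average is bit-identical regardless of direction order.
#' Directions with no valid voxel pair are excluded from the average and
#' reported in the `n_directions` attribute.
#'
#' @param q Quantized volume ([quantize_gray_levels()]).
#' @param ng Number of gray levels; default from `attr(q, "ng")`.
#' @param ... Passed to [glcm_features()].
#' @return One-row tibble of the eight direction-averaged features, with
#'   attribute `n_directions` (number of directions contributing).
#' @export
rotation_invariant_features <- function(q, ng = attr(q, "ng"), ...) {
  offs <- glcm_offsets()
  rows <- vector("list", nrow(offs))
  for (d in seq_len(nrow(offs))) {
    g <- build_glcm(q, offs[d, ], ng = ng)
    if (!is.null(g)) rows[[d]] <- glcm_features_vec(g$p, g$ng, ...)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) abort("No direction yields a valid voxel pair.")
  feats <- do.call(rbind, rows)
  avg <- apply(feats, 2, function(v) {
    v <- sort(v, na.last = NA) # order-independent sum; drop undefined values
    if (length(v) == 0) NA_real_ else sum(v) / length(v)
  })
  out <- tibble::as_tibble(as.list(avg))
  attr(out, "n_directions") <- length(rows)
  out
}
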