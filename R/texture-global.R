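#' Global (first-order) histogram features of an ROI
#'
#' Variance, skewness and excess kurtosis of the in-ROI intensity
#' distribution. By default the moments are computed from a binned histogram
#' (bin centers weighted by bin probabilities, bin count from
#' [choose_histogram_bins()] unless given), matching histogram-based texture
#' pipelines; `method = "raw"` uses the raw sample moments instead. Moments
#' are population moments (denominator `n`); skewness is `m3 / m2^1.5` and
#' kurtosis is the excess `m4 / m2^2 - 3`, so a Gaussian scores 0. A
#' zero-variance ROI has variance 0 and undefined (`NA`) skewness and
#' kurtosis — undefined moments are flagged, never silently zeroed.
#'
#' @param values Numeric vector of in-ROI intensities (>= 3 finite values).
#' @param method `"binned"` or `"raw"`.
#' @param n_bins Histogram bin count; default chosen by
#'   [choose_histogram_bins()].
#' @return A one-row tibble: `variance_global`, `skewness_global`,
#'   `kurtosis_global`, `n_voxels`, `n_bins`.
#' @export
#' @examples
#' global_features(rnorm(1e4), method = "raw")
global_features <- function(values, method = c("binned", "raw"), n_bins = NULL) {
  method <- match.arg(method)
  v <- values[is.finite(values)]
  if (length(v) < 3) abort("Need at least 3 finite values.")
  n <- length(v)

  if (diff(range(v)) == 0) {
    return(tibble::tibble(
      variance_global = 0, skewness_global = NA_real_,
      kurtosis_global = NA_real_, n_voxels = n, n_bins = NA_integer_
    ))
  }

  if (method == "binned") {
    if (is.null(n_bins)) n_bins <- choose_histogram_bins(v)
    edges <- seq(min(v), max(v), length.out = n_bins + 1)
    centers <- (edges[-1] + edges[-length(edges)]) / 2
    idx <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1), n_bins)
    p <- tabulate(idx, nbins = n_bins) / n
    mu <- sum(p * centers)
    d <- centers - mu
    m2 <- sum(p * d^2); m3 <- sum(p * d^3); m4 <- sum(p * d^4)
    nb <- as.integer(n_bins)
  } else {
    mu <- mean(v)
    d <- v - mu
    m2 <- mean(d^2); m3 <- mean(d^3); m4 <- mean(d^4)
    nb <- NA_integer_
  }

  if (m2 <= 0) {
    skew <- NA_real_; kurt <- NA_real_
  } else {
    skew <- m3 / m2^1.5
    kurt <- m4 / m2^2 - 3
  }
  tibble::tibble(
    variance_global = m2, skewness_global = skew, kurtosis_global = kurt,
    n_voxels = n, n_bins = nb
  )
}
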