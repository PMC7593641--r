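#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the pairwise post-hoc table of an ANOVA
#'
#' @param x An `mtx_anova` object.
#' @param ... Unused.
#' @return Tibble of pairwise comparisons with raw and Bonferroni-adjusted
#'   p-values.
#' @export
tidy.mtx_anova <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(feature = x$feature, grouping = x$group),
    x$posthoc
  )
}

#' One-row summary of an ANOVA
#'
#' @param x An `mtx_anova` object.
#' @param ... Unused.
#' @return One-row tibble with the F statistic, degrees of freedom, p-value
#'   and sums of squares.
#' @export
glance.mtx_anova <- function(x, ...) {
  tibble::tibble(
    feature = x$feature, grouping = x$group,
    statistic = x$f_statistic, df = x$df1, df_residual = x$df2,
    p_value = x$p_value,
    ss_between = x$ss_between, ss_within = x$ss_within,
    welch = x$welch
  )
}

#' @export
print.mtx_anova <- function(x, ...) {
  cat(sprintf(
    "<mtx_anova> %s by %s: F(%d, %.4g) = %.4g, p = %.4g%s\n",
    x$feature, x$group, x$df1, x$df2, x$f_statistic, x$p_value,
    if (x$welch) " (Welch)" else ""
  ))
  print(x$summary)
  invisible(x)
}

#' Tidy the coefficient table of an adjusted sex comparison
#'
#' @param x An `mtx_glm` object.
#' @param ... Unused.
#' @return Tibble of model coefficients.
#' @export
tidy.mtx_glm <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(feature = x$feature), x$coefficients)
}

#' One-row summary of an adjusted sex comparison
#'
#' @param x An `mtx_glm` object.
#' @param ... Unused.
#' @return One-row tibble with the sex effect (male minus female), its SE and
#'   p-value.
#' @export
glance.mtx_glm <- function(x, ...) {
  tibble::tibble(
    feature = x$feature,
    sex_effect = x$sex_effect, std_error = x$sex_se, p_value = x$p_value,
    sigma = x$sigma, df_residual = x$df_residual, n = x$n
  )
}

#' @export
print.mtx_glm <- function(x, ...) {
  cat(sprintf(
    "<mtx_glm> %s ~ sex + %s: sex effect (male - female) = %.4g (SE %.3g), p = %.4g\n",
    x$feature, paste(x$covariates, collapse = " + "),
    x$sex_effect, x$sex_se, x$p_value
  ))
  print(x$adjusted_means)
  invisible(x)
}
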