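#' Assign age groups by decade bins
#'
#' Adds (or recomputes) the `age_group` column from `age` using the bins
#' 20--29, 30--39, 40--49, 50--59 and >= 60 years (groups 1..5).
#'
#' @param data Data frame with an `age` column.
#' @return The data with an integer `age_group` column.
#' @export
add_age_group <- function(data) {
  if (!"age" %in% names(data)) abort("`data` needs an `age` column.")
  if (any(data$age < 20, na.rm = TRUE)) abort("Ages below 20 are outside the group bins.")
  dplyr::mutate(
    data,
    age_group = pmin(floor((.data$age - 20) / 10) + 1, 5)
  )
}

#' Average each subject's features over vertebral levels
#'
#' Collapses the long per-(subject, level) feature table to one row per
#' subject by averaging the feature columns over the available levels
#' (available-case analysis: subjects missing a level are averaged over the
#' levels they have).
#'
#' @param data Long feature table, e.g. from [extract_cohort_features()].
#' @param features Feature columns to average; default [feature_names()].
#' @return Tibble with one row per subject: covariates, `n_levels`, features.
#' @export
average_levels <- function(data, features = feature_names()) {
  features <- intersect(features, names(data))
  dplyr::summarise(
    dplyr::group_by(data, .data$id),
    dplyr::across(dplyr::any_of(c("sex", "age", "age_group", "bmi")), dplyr::first),
    n_levels = dplyr::n(),
    dplyr::across(dplyr::all_of(features), ~ mean(.x, na.rm = TRUE)),
    .groups = "drop"
  )
}

#' Kolmogorov--Smirnov normality screen
#'
#' One-sample KS test of the values against a normal with the sample mean
#' and SD. Estimating the parameters from the same sample makes the plain KS
#' p-value anticonservative; `method = "lilliefors"` applies the Lilliefors
#' correction instead.
#'
#' @param values Numeric vector (>= 5 finite values, nonzero variance).
#' @param method `"ks"` (plain, fitted-parameter) or `"lilliefors"`.
#' @return One-row tibble: `n`, `statistic`, `p_value`, `method`.
#' @export
ks_normality <- function(values, method = c("ks", "lilliefors")) {
  method <- match.arg(method)
  v <- values[is.finite(values)]
  if (length(v) < 5) abort("Need at least 5 finite values.")
  if (sd(v) == 0) abort("Zero-variance input: normality is undefined.")
  if (method == "ks") {
    res <- suppressWarnings(stats::ks.test(v, "pnorm", mean(v), sd(v)))
  } else {
    res <- nortest::lillie.test(v)
  }
  tibble::tibble(
    n = length(v),
    statistic = unname(res$statistic),
    p_value = res$p.value,
    method = method
  )
}

#' Screen every feature for normality
#'
#' @param data Feature table.
#' @param features Columns to screen.
#' @param method See [ks_normality()].
#' @return Tibble with one row per feature.
#' @export
feature_normality <- function(data, features = feature_names(),
                              method = "ks") {
  features <- intersect(features, names(data))
  purrr::map_dfr(features, function(f) {
    v <- data[[f]]
    v <- v[is.finite(v)]
    if (length(v) < 5 || sd(v) == 0) {
      return(tibble::tibble(
        feature = f, n = length(v), statistic = NA_real_,
        p_value = NA_real_, method = method
      ))
    }
    dplyr::bind_cols(tibble::tibble(feature = f), ks_normality(v, method))
  })
}

#' One-way ANOVA with Bonferroni-adjusted post-hoc comparisons
#'
#' Classical (equal-variance) one-way analysis of variance computed from the
#' sums of squares: `SS_between = sum n_g (xbar_g - xbar)^2`, `SS_within =
#' sum (n_g - 1) s_g^2`, `F = MS_between / MS_within`. Pairwise post-hoc
#' comparisons use t statistics with the pooled within-group variance
#' (`MS_within`) and Bonferroni-adjusted p-values, `p_adj = min(1, m * p)`
#' with `m` the number of pairs. `welch = TRUE` substitutes Welch's
#' heteroscedastic F for the omnibus test.
#'
#' @param data Data frame.
#' @param feature Name of the response column.
#' @param group Name of the grouping column (e.g. `"level"` for vertebral
#'   levels, `"age_group"` for age groups).
#' @param welch Use Welch's ANOVA for the omnibus test.
#' @return An object of class `mtx_anova` with [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
anova_across_groups <- function(data, feature, group, welch = FALSE) {
  v <- data[[feature]]
  g <- as.character(data[[group]])
  ok <- is.finite(v) & !is.na(g)
  v <- v[ok]; g <- g[ok]
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warn(sprintf(
      "Excluding group(s) with fewer than 2 observations: %s",
      paste(small, collapse = ", ")
    ))
    keep <- !(g %in% small)
    v <- v[keep]; g <- g[keep]
  }
  groups <- sort(unique(g))
  if (length(groups) < 2) abort("Need at least 2 groups with >= 2 observations.")

  n_g <- vapply(groups, function(x) sum(g == x), numeric(1))
  m_g <- vapply(groups, function(x) mean(v[g == x]), numeric(1))
  s_g <- vapply(groups, function(x) sd(v[g == x]), numeric(1))
  n <- length(v)
  k <- length(groups)
  grand <- mean(v)
  ss_between <- sum(n_g * (m_g - grand)^2)
  ss_within <- sum((n_g - 1) * s_g^2)
  df1 <- k - 1
  df2 <- n - k
  ms_within <- ss_within / df2

  if (welch) {
    w <- n_g / s_g^2
    mw <- sum(w * m_g) / sum(w)
    f_stat <- sum(w * (m_g - mw)^2) / df1 /
      (1 + 2 * (k - 2) / (k^2 - 1) * sum((1 - w / sum(w))^2 / (n_g - 1)))
    df2_eff <- (k^2 - 1) / (3 * sum((1 - w / sum(w))^2 / (n_g - 1)))
    p <- pf(f_stat, df1, df2_eff, lower.tail = FALSE)
  } else {
    f_stat <- if (ss_within == 0) {
      if (ss_between == 0) 0 else Inf
    } else {
      (ss_between / df1) / ms_within
    }
    df2_eff <- df2
    p <- if (is.infinite(f_stat)) 0 else pf(f_stat, df1, df2, lower.tail = FALSE)
  }

  pairs <- utils::combn(groups, 2)
  m <- ncol(pairs)
  posthoc <- purrr::map_dfr(seq_len(m), function(idx) {
    a <- pairs[1, idx]; b <- pairs[2, idx]
    ia <- match(a, groups); ib <- match(b, groups)
    se <- sqrt(ms_within * (1 / n_g[ia] + 1 / n_g[ib]))
    tval <- if (se == 0) NA_real_ else (m_g[ia] - m_g[ib]) / se
    praw <- if (is.na(tval)) NA_real_ else 2 * pt(abs(tval), df2, lower.tail = FALSE)
    tibble::tibble(
      group1 = a, group2 = b, diff = m_g[ia] - m_g[ib],
      t = tval, p_raw = praw
    )
  })
  posthoc$p_adj <- pmin(posthoc$p_raw * m, 1)

  structure(
    list(
      feature = feature, group = group,
      summary = tibble::tibble(group = groups, n = n_g, mean = m_g, sd = s_g),
      f_statistic = f_stat, df1 = df1, df2 = df2_eff, p_value = p,
      ss_between = ss_between, ss_within = ss_within,
      ss_total = sum((v - grand)^2),
      welch = welch, posthoc = posthoc
    ),
    class = "mtx_anova"
  )
}

#' Sex comparison adjusted for covariates via a general linear model
#'
#' Fits `feature ~ sex + covariates` by ordinary least squares (QR solve of
#' the design matrix) and reports the sex coefficient (male minus female),
#' its standard error, t statistic and two-sided p-value, plus
#' covariate-adjusted group means (predictions at the overall covariate
#' means). With no covariates this reduces to the two-sample comparison of
#' raw means.
#'
#' @param data Data frame with `sex` plus the covariate columns.
#' @param feature Response column name.
#' @param covariates Covariate column names (default `c("age", "bmi")`).
#' @return An object of class `mtx_glm` with `tidy()`/`glance()` methods.
#' @export
adjusted_sex_comparison <- function(data, feature, covariates = c("age", "bmi")) {
  need <- c(feature, "sex", covariates)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) abort(paste("Missing columns:", paste(miss, collapse = ", ")))
  d <- data[stats::complete.cases(data[need]), need]
  if (length(unique(d$sex)) < 2) abort("Both sexes must be present.")
  for (cv in covariates) {
    if (sd(d[[cv]]) == 0) abort(sprintf("Covariate `%s` is constant.", cv))
  }
  sex_male <- as.numeric(d$sex == "male")
  X <- cbind(`(Intercept)` = 1, sex_male = sex_male)
  for (cv in covariates) X <- cbind(X, d[[cv]])
  colnames(X) <- c("(Intercept)", "sex_male", covariates)
  y <- d[[feature]]

  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    abort(sprintf("Design is rank deficient; collinear column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qrx, y)
  res <- y - drop(X %*% beta)
  df_res <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df_res
  xtx_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(sigma2 * diag(xtx_inv))
  names(se) <- colnames(X)
  tvals <- beta / se
  pvals <- 2 * pt(abs(tvals), df_res, lower.tail = FALSE)

  # adjusted means: prediction per sex at the pooled covariate means
  cov_means <- vapply(covariates, function(cv) mean(d[[cv]]), numeric(1))
  base <- sum(c(1, 0, cov_means) * beta)
  adj <- tibble::tibble(
    sex = c("female", "male"),
    n = c(sum(sex_male == 0), sum(sex_male == 1)),
    raw_mean = c(mean(y[sex_male == 0]), mean(y[sex_male == 1])),
    adjusted_mean = c(base, base + beta[["sex_male"]])
  )

  structure(
    list(
      feature = feature, covariates = covariates,
      coefficients = tibble::tibble(
        term = colnames(X), estimate = unname(beta), std_error = unname(se),
        statistic = unname(tvals), p_value = unname(pvals)
      ),
      sex_effect = beta[["sex_male"]],
      sex_se = se[["sex_male"]],
      p_value = pvals[["sex_male"]],
      adjusted_means = adj,
      sigma = sqrt(sigma2), df_residual = df_res, n = nrow(X)
    ),
    class = "mtx_glm"
  )
}

#' Group mean/SD summary table
#'
#' Reproduces the mean (SD, N) layout of cross-sectional cohort tables for
#' any grouping.
#'
#' @param data Data frame.
#' @param features Feature columns to summarize.
#' @param group Grouping column name.
#' @return Tibble: `feature`, one row per (feature, group) with `n`, `mean`,
#'   `sd`.
#' @export
summarize_groups <- function(data, features, group) {
  features <- intersect(features, names(data))
  if (nrow(data) == 0) abort("Empty input.")
  long <- tidyr::pivot_longer(
    data[, c(group, features)],
    dplyr::all_of(features),
    names_to = "feature", values_to = "value"
  )
  dplyr::summarise(
    dplyr::group_by(long, .data$feature, .data[[group]]),
    n = sum(is.finite(.data$value)),
    mean = mean(.data$value, na.rm = TRUE),
    sd = sd(.data$value, na.rm = TRUE),
    .groups = "drop"
  )
}
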