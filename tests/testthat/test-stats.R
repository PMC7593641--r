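test_that("age groups follow the decade bins", {
  d <- tibble::tibble(age = c(20, 29, 30, 45, 59, 60, 74))
  g <- add_age_group(d)$age_group
  expect_equal(g, c(1, 1, 2, 3, 4, 5, 5))
  expect_error(add_age_group(tibble::tibble(age = 15)), "below 20")
})

test_that("KS normality screen behaves on known distributions", {
  # uniform data vs fitted normal: rejected at alpha = 0.05 for n = 1e4
  set.seed(12)
  u <- runif(1e4)
  res <- ks_normality(u)
  expect_lt(res$p_value, 0.05)

  # two-point symmetric data: KS distance to the fitted normal has a
  # closed form sup |F_hat - Phi|; for +/-1 (mean 0, sd = 1 by population...)
  v <- rep(c(-1, 1), 50)
  res <- ks_normality(v)
  # empirical CDF jumps to 0.5 at -1; fitted normal uses sample sd
  s <- sd(v)
  want <- max(
    abs(0.5 - pnorm(-1, 0, s)),
    abs(pnorm(-1, 0, s) - 0),
    abs(1 - pnorm(1, 0, s)),
    abs(pnorm(1, 0, s) - 0.5)
  )
  expect_equal(res$statistic, want, tolerance = 1e-10)

  # normal data: mostly not rejected (Lilliefors variant also runs)
  set.seed(13)
  nrm <- rnorm(500)
  expect_gt(ks_normality(nrm)$p_value, 0.05)
  expect_gt(ks_normality(nrm, method = "lilliefors")$p_value, 0.01)

  expect_error(ks_normality(c(1, 2, 3, 4)), "at least 5")
  expect_error(ks_normality(rep(1, 10)), "variance")
})

test_that("one-way ANOVA from sums of squares matches stats::aov and F = t^2", {
  set.seed(20)
  d <- tibble::tibble(
    value = c(rnorm(12, 0), rnorm(15, 0.8), rnorm(10, -0.3)),
    grp = rep(c("a", "b", "c"), c(12, 15, 10))
  )
  res <- anova_across_groups(d, "value", "grp")
  ref <- summary(stats::aov(value ~ grp, data = d))[[1]]
  expect_equal(res$f_statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)

  # sums-of-squares identity
  expect_equal(res$ss_total, res$ss_between + res$ss_within, tolerance = 1e-10)

  # two equal-size groups: F equals the square of the pooled t statistic
  d2 <- tibble::tibble(
    value = c(rnorm(20, 0), rnorm(20, 0.5)),
    grp = rep(c("a", "b"), each = 20)
  )
  res2 <- anova_across_groups(d2, "value", "grp")
  tt <- stats::t.test(value ~ grp, data = d2, var.equal = TRUE)
  expect_equal(res2$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res2$p_value, tt$p.value, tolerance = 1e-10)

  # identical observations: F = 0
  d3 <- tibble::tibble(value = rep(5, 12), grp = rep(c("a", "b"), 6))
  expect_equal(anova_across_groups(d3, "value", "grp")$f_statistic, 0)

  # undersized groups are excluded with a warning
  d4 <- tibble::tibble(value = rnorm(11), grp = c(rep("a", 5), rep("b", 5), "c"))
  expect_warning(res4 <- anova_across_groups(d4, "value", "grp"), "fewer than 2")
  expect_identical(res4$summary$group, c("a", "b"))
})

test_that("Bonferroni post-hoc p-values are capped multiples of the raw values", {
  set.seed(30)
  d <- tibble::tibble(
    value = rnorm(40, rep(c(0, 0.1, 1.5, 0.2), each = 10)),
    grp = rep(letters[1:4], each = 10)
  )
  res <- anova_across_groups(d, "value", "grp")
  ph <- res$posthoc
  m <- nrow(ph) # 6 pairs
  expect_identical(m, 6L)
  expect_equal(ph$p_adj, pmin(ph$p_raw * m, 1))
  expect_true(all(ph$p_adj >= ph$p_raw))
  expect_true(all(ph$p_adj <= 1))

  tidied <- tidy(res)
  expect_true(all(c("group1", "group2", "p_adj") %in% names(tidied)))
  expect_identical(nrow(glance(res)), 1L)
})

test_that("ANOVA type-I error is calibrated under the null", {
  set.seed(41)
  reps <- 600
  rej <- 0
  for (r in seq_len(reps)) {
    d <- tibble::tibble(value = rnorm(100), grp = rep(1:5, each = 20))
    if (anova_across_groups(d, "value", "grp")$p_value < 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / reps - 0.05), 0.025)
})

test_that("covariate-adjusted sex comparison matches lm and recovers effects", {
  set.seed(50)
  n <- 200
  d <- tibble::tibble(
    sex = rep(c("female", "male"), each = n / 2),
    age = runif(n, 20, 75),
    bmi = rnorm(n, 26, 4)
  )
  d$contrast <- 50 + 2.0 * (d$sex == "male") + 0.05 * d$age - 0.1 * d$bmi + rnorm(n, 0, 1)
  res <- adjusted_sex_comparison(d, "contrast")

  ref <- stats::lm(contrast ~ I(sex == "male") + age + bmi, data = d)
  rs <- summary(ref)$coefficients
  expect_equal(res$sex_effect, rs[2, 1], tolerance = 1e-10)
  expect_equal(res$sex_se, rs[2, 2], tolerance = 1e-10)
  expect_equal(res$p_value, rs[2, 4], tolerance = 1e-10)
  expect_lt(abs(res$sex_effect - 2.0), 3 * res$sex_se)

  # balanced covariates: adjusted difference equals the raw mean difference
  d2 <- d
  d2$age <- rep(c(30, 40, 50, 60), n / 4)
  d2$bmi <- rep(25, n)
  expect_error(adjusted_sex_comparison(d2, "contrast"), "constant")
  d2$bmi <- rep(c(22, 30), n / 2)
  res2 <- adjusted_sex_comparison(d2, "contrast")
  raw_diff <- mean(d2$contrast[d2$sex == "male"]) - mean(d2$contrast[d2$sex == "female"])
  expect_equal(res2$sex_effect, raw_diff, tolerance = 1e-10)

  # rank-deficient design names the collinear column
  d3 <- d
  d3$bmi <- d3$age
  expect_error(adjusted_sex_comparison(d3, "contrast"), "bmi")

  expect_error(
    adjusted_sex_comparison(dplyr::filter(d, sex == "male"), "contrast"),
    "Both sexes"
  )
})

test_that("null sex-effect p-values are approximately uniform", {
  set.seed(60)
  reps <- 400
  pv <- numeric(reps)
  base <- tibble::tibble(
    sex = rep(c("female", "male"), each = 50),
    age = runif(100, 20, 75),
    bmi = rnorm(100, 26, 4)
  )
  for (r in seq_len(reps)) {
    base$y <- rnorm(100)
    pv[r] <- adjusted_sex_comparison(base, "y")$p_value
  }
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("group summaries reproduce hand-computed means", {
  d <- tibble::tibble(
    grp = c("x", "x", "y", "y", "y"),
    f1 = c(1, 3, 10, 20, 30)
  )
  s <- summarize_groups(d, "f1", "grp")
  expect_equal(s$mean[s$grp == "x"], 2)
  expect_equal(s$mean[s$grp == "y"], 20)
  expect_equal(s$sd[s$grp == "y"], 10)
  expect_equal(s$n, c(2L, 3L))

  one <- summarize_groups(d[1:2, ], "f1", "grp")
  expect_identical(nrow(one), 1L)
  expect_error(summarize_groups(d[0, ], "f1", "grp"), "Empty")
})

test_that("level averaging uses available cases per subject", {
  d <- tibble::tibble(
    id = c("a", "a", "a", "b"),
    sex = "female", age = 30, bmi = 25,
    level = c("L1", "L2", "L3", "L4"),
    pdff_mean = c(10, 20, 30, 50),
    contrast = c(1, 2, 3, 4)
  )
  avg <- average_levels(d, features = c("pdff_mean", "contrast"))
  expect_equal(avg$pdff_mean[avg$id == "a"], 20)
  expect_equal(avg$n_levels, c(3L, 1L))
  expect_equal(avg$pdff_mean[avg$id == "b"], 50)
})
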