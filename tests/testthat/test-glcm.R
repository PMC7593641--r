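test_that("the direction set covers the 26-neighborhood once per +/- pair", {
  offs <- glcm_offsets()
  expect_identical(nrow(offs), 13L)
  # no offset is the negative of another; together with negatives: 26 unique
  all26 <- rbind(offs, -offs)
  expect_identical(nrow(unique(all26)), 26L)
  expect_setequal(sqrt(rowSums(offs^2)), c(1, sqrt(2), sqrt(3)))
})

test_that("co-occurrence counting matches exhaustive pair enumeration", {
  # 1x1x2 ROI with levels (1, 2): p(1,2) = p(2,1) = 0.5
  q <- array(c(1L, 2L), c(1, 1, 2))
  attr(q, "ng") <- 2L
  g <- build_glcm(q, c(0, 0, 1))
  expect_equal(g$p, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_identical(g$n_pairs, 2L)

  # constant ROI: all mass at p(g, g)
  q <- array(3L, c(3, 3, 3)); attr(q, "ng") <- 4L
  g <- build_glcm(q, c(1, 0, 0))
  expect_equal(g$p[3, 3], 1)
  expect_equal(sum(g$p), 1)

  # random masked volumes: exact equality with the brute-force oracle
  set.seed(77)
  offs <- glcm_offsets()
  for (rep in 1:10) {
    q <- random_quantized_volume(sample(3:6, 3, TRUE), ng = sample(2:6, 1))
    for (d in sample(nrow(offs), 4)) {
      got <- build_glcm(q, offs[d, ])
      want <- oracle_glcm_counts(q, offs[d, ], attr(q, "ng"))
      if (is.null(got)) {
        expect_true(all(want == 0))
      } else {
        expect_identical(got$counts, want)
        expect_equal(sum(got$p), 1, tolerance = 1e-12)
        expect_equal(got$p, t(got$p)) # symmetric
      }
    }
  }

  # single-voxel ROI: no valid pair, flagged missing
  q <- array(0L, c(3, 3, 3)); q[2, 2, 2] <- 1L; attr(q, "ng") <- 2L
  expect_null(build_glcm(q, c(0, 0, 1)))
})

test_that("feature formulas reproduce hand-evaluated matrices", {
  # strict two-level alternation: 2x2 matrix with p(1,2) = p(2,1) = 0.5
  q <- array(rep(c(1L, 2L), 4), c(1, 1, 8))
  attr(q, "ng") <- 2L
  f <- glcm_features(build_glcm(q, c(0, 0, 1)))
  expect_equal(f$contrast, 1)
  expect_equal(f$dissimilarity, 1)
  expect_equal(f$energy, 0.5)
  expect_equal(f$entropy, 1) # 1 bit
  expect_equal(f$homogeneity, 0.5) # 2 * (0.5 / (1 + 1))
  expect_equal(f$correlation, -1)
  expect_equal(f$sum_average, 3)
  expect_equal(f$variance_glcm, 0.25)

  # constant ROI: analytic single-entry values, correlation undefined
  q <- array(2L, c(2, 2, 2)); attr(q, "ng") <- 3L
  f <- glcm_features(build_glcm(q, c(1, 0, 0)))
  expect_equal(f$energy, 1)
  expect_equal(f$entropy, 0)
  expect_equal(f$contrast, 0)
  expect_equal(f$dissimilarity, 0)
  expect_equal(f$homogeneity, 1)
  expect_equal(f$variance_glcm, 0)
  expect_equal(f$sum_average, 4) # 2g at g = 2
  expect_true(is.na(f$correlation))

  # uniform GLCM over Ng = 4: closed-form sums
  g <- list(p = matrix(1 / 16, 4, 4), ng = 4L, offset = c(1L, 0L, 0L))
  class(g) <- "glcm"
  f <- glcm_features(g)
  expect_equal(f$energy, 1 / 16)
  expect_equal(f$entropy, 4)
  expect_equal(f$correlation, 0)

  # inverse-difference-moment variant on the alternation matrix
  q <- array(rep(c(1L, 2L), 4), c(1, 1, 8)); attr(q, "ng") <- 2L
  f <- glcm_features(build_glcm(q, c(0, 0, 1)), homogeneity_kind = "idm")
  expect_equal(f$homogeneity, 0.5) # |i-j| = 1 so both variants agree here
  # natural-log entropy differs by the log(2) factor
  f_nat <- glcm_features(build_glcm(q, c(0, 0, 1)), entropy_base = exp(1))
  expect_equal(f_nat$entropy, log(2))
})

test_that("per-direction features match the term-by-term oracle on random volumes", {
  set.seed(31)
  offs <- glcm_offsets()
  for (rep in 1:8) {
    q <- random_quantized_volume(c(5, 6, 5), ng = 5)
    for (d in sample(nrow(offs), 3)) {
      g <- build_glcm(q, offs[d, ])
      got <- unlist(glcm_features(g))
      want <- oracle_glcm_features(g$p, g$ng)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("direction averaging equals the mean of brute-force per-direction values", {
  set.seed(55)
  q <- random_quantized_volume(c(6, 6, 6), ng = 6)
  offs <- glcm_offsets()
  per_dir <- sapply(seq_len(nrow(offs)), function(d) {
    counts <- oracle_glcm_counts(q, offs[d, ], 6L)
    oracle_glcm_features(counts / sum(counts), 6L)
  })
  want <- rowMeans(per_dir)
  got <- rotation_invariant_features(q)
  expect_equal(unlist(got), want, tolerance = 1e-12)
  expect_identical(attr(got, "n_directions"), 13L)
})

test_that("averaged features are invariant under signed axis permutations", {
  set.seed(21)
  q <- random_quantized_volume(c(5, 6, 7), ng = 5)
  ref <- rotation_invariant_features(q)
  for (op in signed_permutations()[c(2, 7, 19, 30, 48)]) {
    qt <- apply_signed_permutation(q, op)
    expect_identical(unlist(rotation_invariant_features(qt)), unlist(ref))
  }
})

test_that("gray-level shift moves sum average and mean but not difference features", {
  set.seed(61)
  q <- random_quantized_volume(c(5, 5, 5), ng = 4)
  shift <- 3L
  q2 <- q
  q2[q2 > 0] <- q2[q2 > 0] + shift
  attr(q2, "ng") <- attr(q, "ng") + shift
  a <- rotation_invariant_features(q)
  b <- rotation_invariant_features(q2)
  expect_equal(b$sum_average, a$sum_average + 2 * shift, tolerance = 1e-10)
  expect_equal(b$variance_glcm, a$variance_glcm, tolerance = 1e-10)
  expect_equal(b$contrast, a$contrast, tolerance = 1e-12)
  expect_equal(b$dissimilarity, a$dissimilarity, tolerance = 1e-12)
  expect_equal(b$energy, a$energy, tolerance = 1e-12)
  expect_equal(b$entropy, a$entropy, tolerance = 1e-12)
  expect_equal(b$homogeneity, a$homogeneity, tolerance = 1e-12)
})

test_that("extracted feature rows have the full schema and expected degeneracies", {
  ph <- generate_phantom(phantom_spec(local_sd = 0, noise_sd = 0, seed = 2))
  row <- extract_features(ph$map, ph$mask, 1)
  expect_true(all(feature_names() %in% names(row)))
  expect_equal(row$contrast, 0)
  expect_equal(row$pdff_mean, phantom_spec()$level_means[1])
  expect_equal(row$variance_global, 0)
  expect_true(is.na(row$correlation))

  # higher heterogeneity amplitude raises contrast and dissimilarity
  lo <- generate_phantom(phantom_spec(local_sd = 5, noise_sd = 1, seed = 3))
  hi <- generate_phantom(phantom_spec(local_sd = 12, noise_sd = 1, seed = 3))
  r_lo <- extract_features(lo$map, lo$mask, 2)
  r_hi <- extract_features(hi$map, hi$mask, 2)
  expect_gte(r_hi$contrast, r_lo$contrast)
  expect_gte(r_hi$dissimilarity, r_lo$dissimilarity)

  expect_error(extract_features(ph$map, ph$mask, 9), "not present")
})
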