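test_that("fat signal coefficient matches direct evaluation of the phase sum", {
  sp <- default_fat_spectrum()
  expect_equal(sum(sp$amplitude), 1, tolerance = 1e-12)

  # t = 0: all phases zero
  expect_equal(fat_signal_coefficient(0, sp, 3), 1 + 0i)

  # single peak at -3.4 ppm, 3 T: frequency ~ -434.3 Hz, and after one full
  # period the phase wraps back to ~1
  one <- data.frame(shift_ppm = -3.4, amplitude = 1)
  df <- 42.577478518 * 3 * (-3.4)
  expect_equal(df, -434.29, tolerance = 1e-4)
  expect_equal(fat_signal_coefficient(1 / abs(df), one, 3), 1 + 0i, tolerance = 1e-9)

  # brute-force check on the multi-peak spectrum at an arbitrary time
  t <- 2.5e-3
  expected <- sum(sp$amplitude * exp(2i * pi * 42.577478518 * 3 * sp$shift_ppm * t))
  expect_equal(fat_signal_coefficient(t, sp, 3), expected)

  # conjugate-symmetric two-peak spectrum gives a real coefficient
  sym <- data.frame(shift_ppm = c(-2, 2), amplitude = c(0.5, 0.5))
  ts <- seq(0, 0.01, length.out = 11)
  expect_equal(Im(fat_signal_coefficient(ts, sym, 3)), rep(0, 11), tolerance = 1e-12)

  # magnitude never exceeds 1
  expect_true(all(Mod(fat_signal_coefficient(seq(0, 0.02, by = 1e-4), sp, 3)) <= 1 + 1e-12))

  expect_error(
    fat_signal_coefficient(0, data.frame(shift_ppm = -3.4, amplitude = 0.9), 3),
    "sum to 1"
  )
})

test_that("echo simulation reproduces hand-computed special cases", {
  acq <- acquisition_params()
  expect_equal(echo_times(acq) * 1e3, seq(1.4, by = 1.1, length.out = 8))

  # pure water, on resonance, no decay: constant 1
  s <- simulate_echo_series(voxel_model(W = 1, F = 0), acq)
  expect_equal(s, rep(1 + 0i, 8))

  # pure fat: s_n = c_F(TE_n), by direct summation over peaks
  s <- simulate_echo_series(voxel_model(W = 0, F = 1), acq)
  te <- echo_times(acq)
  sp <- acq$fat_peaks
  expected <- vapply(
    te,
    function(tt) sum(sp$amplitude * exp(2i * pi * 42.577478518 * 3 * sp$shift_ppm * tt)),
    complex(1)
  )
  expect_equal(s, expected)

  # R2* decay: strictly decreasing magnitude exp(-R2* TE)
  s <- simulate_echo_series(voxel_model(W = 1, F = 0, r2star = 80), acq)
  expect_equal(Mod(s), exp(-80 * te))
  expect_true(all(diff(Mod(s)) < 0))

  # noiseless call is deterministic; noise honors the seed
  expect_identical(
    simulate_echo_series(voxel_model(1, 0), acq),
    simulate_echo_series(voxel_model(1, 0), acq)
  )
  n1 <- simulate_echo_series(voxel_model(1, 0), acq, noise_sd = 0.1, seed = 7)
  n2 <- simulate_echo_series(voxel_model(1, 0), acq, noise_sd = 0.1, seed = 7)
  expect_identical(n1, n2)
  expect_error(simulate_echo_series(voxel_model(1, 0), acq, noise_sd = -1), "nonnegative")
})

test_that("water-fat fit recovers simulated parameters and PDFF", {
  acq <- acquisition_params()

  truth <- voxel_model(W = 0.6, F = 0.4, psi = 20, r2star = 40)
  fit <- fit_water_fat(simulate_echo_series(truth, acq), acq)
  expect_true(fit$valid)
  expect_equal(fit$W, 0.6, tolerance = 1e-6)
  expect_equal(fit$F, 0.4, tolerance = 1e-6)
  expect_equal(fit$psi, 20, tolerance = 1e-4)
  expect_equal(fit$r2star, 40, tolerance = 1e-4)
  expect_equal(compute_pdff(fit), 40, tolerance = 1e-6)

  # pure fat: PDFF exactly 100
  fit <- fit_water_fat(simulate_echo_series(voxel_model(0, 1), acq), acq)
  expect_equal(compute_pdff(fit), 100, tolerance = 1e-8)

  # residual of a noiseless fit is tiny relative to the signal norm
  s <- simulate_echo_series(voxel_model(0.3, 0.7, psi = -45, r2star = 90), acq)
  fit <- fit_water_fat(s, acq)
  resid <- simulate_echo_series(voxel_model(fit$W, fit$F, fit$psi, fit$r2star), acq) - s
  expect_lt(sqrt(sum(Mod(resid)^2)) / sqrt(sum(Mod(s)^2)), 1e-8)

  expect_error(fit_water_fat(rep(0 + 0i, 8), acq), "All-zero")
  expect_error(
    fit_water_fat(rep(1 + 0i, 3), acquisition_params(n_echoes = 3)),
    ">= 4 echoes"
  )
})

test_that("PDFF arithmetic and scale invariance hold", {
  expect_equal(compute_pdff(voxel_model(1, 1)), 50)
  expect_equal(compute_pdff(voxel_model(1, 0)), 0)
  expect_equal(compute_pdff(voxel_model(3, 1)), 25)
  expect_true(is.na(compute_pdff(voxel_model(0, 0))))

  # multiplying the echo series by a positive constant leaves PDFF unchanged
  acq <- acquisition_params()
  s <- simulate_echo_series(voxel_model(0.55, 0.45, psi = 12, r2star = 30), acq)
  p1 <- compute_pdff(fit_water_fat(s, acq))
  p2 <- compute_pdff(fit_water_fat(7.3 * s, acq))
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("PDFF estimator dispersion shrinks with SNR", {
  acq <- acquisition_params()
  truth <- voxel_model(W = 0.6, F = 0.4, psi = 10, r2star = 50)
  est <- function(snr, n, seed) {
    set.seed(seed)
    vapply(seq_len(n), function(i) {
      s <- simulate_echo_series(truth, acq, noise_sd = 1 / snr)
      compute_pdff(fit_water_fat(s, acq))
    }, numeric(1))
  }
  sd_lo <- sd(est(20, 60, 11))
  sd_hi <- sd(est(100, 60, 11))
  expect_lt(sd_hi, sd_lo)
})

test_that("volume decomposition round-trips a small phantom map", {
  acq <- acquisition_params()
  set.seed(3)
  dm <- c(4, 4, 3)
  truth <- array(runif(prod(dm), 5, 95), dm)
  mask <- array(1L, dm)
  echoes <- simulate_echo_volumes(truth, acq, psi = 15, r2star = 60)
  pdff <- decompose_volume(echoes, acq, mask = mask)
  expect_lt(max(abs(pdff - truth)), 1e-4)

  # all-water volume maps to zero
  echoes0 <- simulate_echo_volumes(array(0, dm), acq)
  pdff0 <- decompose_volume(echoes0, acq)
  expect_equal(as.vector(pdff0), rep(0, prod(dm)), tolerance = 1e-8)
  expect_true(all(pdff0 >= 0 & pdff0 <= 100))

  expect_error(
    decompose_volume(echoes, acq, mask = array(1L, c(2, 2, 2))),
    "shape"
  )
})
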