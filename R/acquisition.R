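#' Default multi-peak fat spectrum
#'
#' Chemical shifts (ppm, relative to the water resonance; negative values lie
#' upfield of water) and relative amplitudes of the triglyceride proton
#' spectrum used for chemical-shift-encoded water--fat separation. The default
#' is a seven-peak table in the style of multi-peak calibrations used for
#' marrow and liver fat quantification, with the dominant methylene resonance
#' split into its 1.30 and 1.60 ppm components. Amplitudes sum to 1.
#'
#' The table is configuration, not hard-coded physics: any data frame with
#' columns `shift_ppm` and `amplitude` (amplitudes summing to 1) can be passed
#' wherever a fat spectrum is accepted.
#'
#' @return A tibble with columns `shift_ppm` and `amplitude`.
#' @export
#' @examples
#' default_fat_spectrum()
default_fat_spectrum <- function() {
  tibble::tibble(
    shift_ppm = c(-3.80, -3.40, -3.10, -2.60, -1.94, -0.39, 0.60),
    amplitude = c(0.088, 0.628, 0.059, 0.128, 0.004, 0.039, 0.054)
  )
}

validate_fat_spectrum <- function(fat_peaks) {
  if (!is.data.frame(fat_peaks) ||
      !all(c("shift_ppm", "amplitude") %in% names(fat_peaks))) {
    abort("`fat_peaks` must be a data frame with columns `shift_ppm` and `amplitude`.")
  }
  if (any(fat_peaks$amplitude < 0)) {
    abort("Fat peak amplitudes must be nonnegative.")
  }
  if (abs(sum(fat_peaks$amplitude) - 1) > 1e-6) {
    abort("Fat peak amplitudes must sum to 1 (relative amplitudes).")
  }
  fat_peaks
}

#' Acquisition parameters for a multi-echo gradient-echo protocol
#'
#' Bundles the echo train and scanner metadata needed by the forward signal
#' model and the water--fat fit. Defaults match a sagittal eight-echo 3D
#' spoiled gradient-echo spine protocol at 3 T with TR/TE1/dTE = 11/1.4/1.1 ms
#' and a 3 degree flip angle (the low flip angle keeps T1 bias negligible, so
#' the signal model omits T1; TR and flip angle are carried as metadata only).
#'
#' @param n_echoes Number of echoes (>= 3).
#' @param te1 First echo time in seconds.
#' @param delta_te Echo spacing in seconds.
#' @param tr Repetition time in seconds (metadata).
#' @param flip_angle Flip angle in degrees (metadata).
#' @param field_strength Main field strength in tesla.
#' @param fat_peaks Fat spectrum table, see [default_fat_spectrum()].
#'
#' @return An object of class `acquisition_params`.
#' @export
#' @examples
#' acq <- acquisition_params()
#' echo_times(acq) * 1e3  # ms: 1.4, 2.5, ..., 9.1
acquisition_params <- function(n_echoes = 8L,
                               te1 = 1.4e-3,
                               delta_te = 1.1e-3,
                               tr = 11e-3,
                               flip_angle = 3,
                               field_strength = 3,
                               fat_peaks = default_fat_spectrum()) {
  if (n_echoes < 3) abort("`n_echoes` must be >= 3.")
  if (te1 <= 0 || delta_te <= 0) abort("`te1` and `delta_te` must be positive.")
  if (field_strength <= 0) abort("`field_strength` must be positive.")
  validate_fat_spectrum(fat_peaks)
  structure(
    list(
      n_echoes = as.integer(n_echoes), te1 = te1, delta_te = delta_te,
      tr = tr, flip_angle = flip_angle, field_strength = field_strength,
      fat_peaks = fat_peaks
    ),
    class = "acquisition_params"
  )
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat(sprintf(
    "<acquisition_params> %d echoes, TE1 = %.3g ms, dTE = %.3g ms, %g T, flip %g deg\n",
    x$n_echoes, x$te1 * 1e3, x$delta_te * 1e3, x$field_strength, x$flip_angle
  ))
  invisible(x)
}

#' Echo times of an acquisition
#'
#' @param acq An [acquisition_params()] object.
#' @return Numeric vector of echo times in seconds, `te1 + (n-1) * delta_te`.
#' @export
echo_times <- function(acq) {
  acq$te1 + (seq_len(acq$n_echoes) - 1) * acq$delta_te
}

#' Complex fat signal coefficient
#'
#' Dephasing coefficient of the fat signal relative to water at time `t`:
#' `c_F(t) = sum_p alpha_p * exp(2i * pi * df_p * t)` where
#' `df_p = gamma * B0 * shift_ppm_p * 1e-6` (Hz) is each peak's chemical-shift
#' frequency offset. At `t = 0` all phases vanish and `c_F(0) = 1`; by the
#' triangle inequality `|c_F(t)| <= 1`.
#'
#' @param t Time(s) in seconds (vectorized).
#' @param fat_peaks Fat spectrum table (`shift_ppm`, `amplitude`; amplitudes
#'   summing to 1).
#' @param field_strength Field strength in tesla.
#' @return Complex vector, one coefficient per element of `t`.
#' @export
#' @examples
#' fat_signal_coefficient(0, default_fat_spectrum(), 3)  # 1+0i
fat_signal_coefficient <- function(t, fat_peaks = default_fat_spectrum(),
                                   field_strength = 3) {
  validate_fat_spectrum(fat_peaks)
  df_hz <- GAMMA_MHZ_PER_T * field_strength * fat_peaks$shift_ppm # MHz * ppm = Hz
  vapply(
    t,
    function(tt) sum(fat_peaks$amplitude * exp(2i * pi * df_hz * tt)),
    complex(1)
  )
}
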