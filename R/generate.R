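#' Generate a synthetic glottal area waveform
#'
#' Kinematic model: each fold's medial edge opens as a rectified sinusoid
#' plus the prephonatory half-gap,
#' `w_side(t) = max(0, baseline_gap + amp_side * m_i * sin(phase_side(t)))`,
#' where `m_i` is the cycle's amplitude multiplier and the right fold lags
#' the left by `2 * pi * phase_offset_frac`. Hemiglottal areas are
#' `glottal_length * w_side(t)` and the total is their sum. Cycle periods
#' and amplitudes carry independent lognormal perturbations calibrated to
#' the spec's local jitter/shimmer targets. Deterministic given `spec$seed`.
#'
#' @param spec An [oscillator_spec()].
#' @param n_cycles Number of nominal cycles to generate; defaults to
#'   `spec$n_cycles`.
#' @return A tibble of class `gaw_df` with columns `t` (s), `area_total`,
#'   `area_left`, `area_right` (px^2) and `length` (px), and an `fs`
#'   attribute (frames/s).
#' @examples
#' gaw <- generate_gaw(oscillator_spec(f0 = 200, n_cycles = 30, seed = 7))
#' range(gaw$area_total)
#' @export
generate_gaw <- function(spec, n_cycles = spec$n_cycles) {
  stopifnot(inherits(spec, "oscillator_spec"))
  n_cycles <- check_count(n_cycles, "n_cycles", min = 1L)
  cyc <- withr::with_seed(spec$seed, draw_cycles(spec, n_cycles))
  ph <- sample_phase(cyc$period, spec$fs_video, phase0 = -pi / 2)
  # fade at the descending zero-crossing: peak and trough both clean
  m <- amp_track(ph, cyc$amp_factor, center = 0.75)
  w_left <- pmax(0, spec$baseline_gap + spec$amp_left * m * sin(ph$phase))
  w_right <- pmax(0, spec$baseline_gap +
                    spec$amp_right * m * sin(ph$phase - 2 * pi * spec$phase_offset_frac))
  out <- tibble(
    t = ph$t,
    area_total = spec$glottal_length * (w_left + w_right),
    area_left = spec$glottal_length * w_left,
    area_right = spec$glottal_length * w_right,
    length = rep(spec$glottal_length, length(ph$t))
  )
  new_gaw(out, fs = spec$fs_video)
}

new_gaw <- function(x, fs) {
  x <- as_tibble(x)
  attr(x, "fs") <- fs
  class(x) <- c("gaw_df", class(x))
  x
}

#' Generate a synthetic acoustic signal
#'
#' Harmonic pulse-train-like source: the sum of `n_harmonics` sine harmonics
#' with 1/k amplitude roll-off on a common perturbed phase track (so the
#' per-cycle period and amplitude perturbations match the spec's local
#' jitter/shimmer targets), plus white noise scaled so that the realized
#' harmonic-to-noise power ratio equals `hnr_target` exactly
#' (`10*log10(P_harmonic / P_noise) = hnr_target`). Deterministic given
#' `spec$seed`.
#'
#' @inheritParams generate_gaw
#' @param n_harmonics Number of harmonics in the source (default 8).
#' @return A tibble with columns `t` (s) and `amplitude` (arbitrary units),
#'   with an `fs` attribute.
#' @export
generate_audio <- function(spec, n_cycles = spec$n_cycles, n_harmonics = 8L) {
  stopifnot(inherits(spec, "oscillator_spec"))
  n_cycles <- check_count(n_cycles, "n_cycles", min = 1L)
  n_harmonics <- check_count(n_harmonics, "n_harmonics", min = 1L)
  if (spec$fs_audio < 4 * spec$f0 * n_harmonics) {
    phono_abort(
      sprintf("fs_audio = %g is below 4 * f0 * n_harmonics = %g; harmonics would alias.",
              spec$fs_audio, 4 * spec$f0 * n_harmonics),
      class = "phonolab_error_aliasing"
    )
  }
  withr::with_seed(spec$seed + 1L, {
    cyc <- draw_cycles(spec, n_cycles)
    ph <- sample_phase(cyc$period, spec$fs_audio, phase0 = 0)
    harm <- numeric(length(ph$t))
    for (k in seq_len(n_harmonics)) {
      harm <- harm + sin(k * ph$phase) / k
    }
    # pulses sit at the cycle starts; fade mid-cycle where the source is weak
    harm <- harm * amp_track(ph, cyc$amp_factor, center = 0.5)
    x <- harm
    if (is.finite(spec$hnr_target)) {
      p_harm <- mean(harm^2)
      noise <- stats::rnorm(length(harm))
      noise <- noise - mean(noise)
      noise <- noise * sqrt(p_harm * 10^(-spec$hnr_target / 10) / mean(noise^2))
      x <- harm + noise
    }
  })
  out <- tibble(t = ph$t, amplitude = x)
  attr(out, "fs") <- spec$fs_audio
  out
}

#' Generate a synthetic subglottal-pressure trace
#'
#' A constant offset `psub_mean` plus a periodic ripple at the fundamental
#' frequency and white noise. The fluctuating part is recentred so the
#' sample mean of the returned trace equals `psub_mean` exactly.
#'
#' @inheritParams generate_gaw
#' @param ripple_frac Ripple amplitude as a fraction of `psub_mean`
#'   (default 0.1).
#' @param noise_frac Noise standard deviation as a fraction of `psub_mean`
#'   (default 0.02).
#' @param duration Trace duration in s; defaults to `n_cycles / f0`.
#' @return A tibble with columns `t` (s) and `p_pa` (Pa), with an `fs`
#'   attribute.
#' @export
generate_pressure <- function(spec, ripple_frac = 0.1, noise_frac = 0.02,
                              duration = spec$n_cycles / spec$f0) {
  stopifnot(inherits(spec, "oscillator_spec"))
  check_number(ripple_frac, "ripple_frac", min = 0)
  check_number(noise_frac, "noise_frac", min = 0)
  check_number(duration, "duration", min = .Machine$double.eps)
  n <- floor(duration * spec$fs_audio)
  t <- (seq_len(n) - 1L) / spec$fs_audio
  fluct <- ripple_frac * spec$psub_mean * sin(2 * pi * spec$f0 * t)
  if (noise_frac > 0) {
    fluct <- fluct + withr::with_seed(
      spec$seed + 2L,
      stats::rnorm(n, sd = noise_frac * spec$psub_mean)
    )
  }
  if (n > 0) fluct <- fluct - mean(fluct)
  out <- tibble(t = t, p_pa = spec$psub_mean + fluct)
  attr(out, "fs") <- spec$fs_audio
  out
}
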