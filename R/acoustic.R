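# Acoustic and aerodynamic measures: F0 and mean subglottal pressure from
# the pressure trace; jitter/shimmer (local), CPP and HNR from the audio.

#' Fundamental frequency and mean subglottal pressure
#'
#' The mean subglottal pressure is the arithmetic mean of the trace. F0 is
#' the reciprocal of the autocorrelation lag maximising the normalized
#' autocorrelation within the plausible period band (60-880 Hz), refined by
#' parabolic interpolation. If no autocorrelation peak reaches 0.3 the
#' signal is considered unvoiced and an error of class
#' `phonolab_error_unvoiced` is raised (carrying the computed `psub` as a
#' field).
#'
#' @param pressure A tibble with columns `t` and `p_pa` (see
#'   [generate_pressure()]), or a numeric vector.
#' @param fs Sampling rate; inferred when `NULL`.
#' @return A one-row tibble with columns `F0` (Hz) and `Psub` (Pa).
#' @export
pressure_parameters <- function(pressure, fs = NULL) {
  fs <- resolve_fs(pressure, fs)
  x <- signal_values(pressure, "p_pa")
  if (length(x) < 0.2 * fs) {
    phono_abort("Pressure trace shorter than 0.2 s; cannot estimate F0.",
                class = "phonolab_error_format")
  }
  psub <- mean(x)
  # attach psub to an unvoiced error so callers still get the mean pressure
  est <- tryCatch(
    estimate_f0_acf(x, fs, min_peak = 0.3),
    phonolab_error_unvoiced = function(e) {
      phono_abort(conditionMessage(e), class = "phonolab_error_unvoiced", psub = psub)
    }
  )
  tibble(F0 = est$f0, Psub = psub)
}

# Mark glottal cycles in an audio signal by period-synchronous peak picking:
# seed on the strongest peak within the first 1.5 nominal periods, then take
# the local maximum in a +/-45% window around each predicted next peak, with
# parabolic refinement of peak time and amplitude.
pick_cycle_peaks <- function(x, fs, f0) {
  p <- fs / f0
  n <- length(x)
  first_win <- seq_len(min(n, max(3L, round(1.5 * p))))
  i <- first_win[which.max(x[first_win])]
  times <- numeric(0)
  amps <- numeric(0)
  # Sub-sample peak refinement on a local spline: tracks even cusp-like
  # pulse peaks precisely (additive noise is interpolated along with the
  # signal, so at low HNR the measured shimmer acquires a positive bias —
  # an inherent property of peak-based local shimmer).
  refine <- function(i) {
    if (i < 6L || i > n - 5L) return(list(t = (i - 1) / fs, a = x[i]))
    idx <- (i - 5L):(i + 5L)
    sf <- stats::splinefun(idx, x[idx], method = "fmm")
    grid <- seq(i - 1, i + 1, by = 1 / 256)
    v <- sf(grid)
    j <- which.max(v)
    if (j > 1L && j < length(v)) {
      pk <- parabolic_peak(v[j - 1L], v[j], v[j + 1L])
      list(t = (grid[j] + pk$offset / 256 - 1) / fs, a = pk$value)
    } else {
      list(t = (grid[j] - 1) / fs, a = v[j])
    }
  }
  while (TRUE) {
    pk <- refine(i)
    times <- c(times, pk$t)
    amps <- c(amps, pk$a)
    lo <- i + round(0.55 * p)
    hi <- i + round(1.45 * p)
    if (hi > n) break
    win <- lo:hi
    i <- win[which.max(x[win])]
  }
  list(times = times, amps = amps)
}

#' Local jitter and shimmer of an acoustic signal
#'
#' Cycle marks are found by period-synchronous peak picking at the
#' autocorrelation-estimated fundamental period. The local measures follow
#' the "two succeeding cycles" definitions:
#' `jitter = mean(|T_i - T_(i+1)|) / mean(T_i) * 100` on cycle durations and
#' `shimmer = mean(|A_i - A_(i+1)|) / mean(A_i) * 100` on per-cycle peak
#' amplitudes.
#'
#' @param audio A tibble with columns `t` and `amplitude` (see
#'   [generate_audio()]), or a numeric vector.
#' @param fs Sampling rate; inferred when `NULL`.
#' @param min_cycles Minimum number of detectable cycles (default 100, the
#'   floor used for stable perturbation measures).
#' @return A one-row tibble with columns `jitt` and `shim` (both %) and
#'   `n_cycles_used`.
#' @export
perturbation_indices <- function(audio, fs = NULL, min_cycles = 100L) {
  fs <- resolve_fs(audio, fs)
  x <- signal_values(audio, "amplitude")
  f0 <- estimate_f0_acf(x, fs, min_peak = 0.3)$f0
  marks <- pick_cycle_peaks(x, fs, f0)
  n_cyc <- length(marks$times) - 1L
  if (n_cyc < min_cycles) {
    phono_abort(
      sprintf("Only %d cycles detected; at least %d are required for jitter/shimmer.",
              n_cyc, min_cycles),
      class = "phonolab_error_insufficient_cycles", n_detected = n_cyc
    )
  }
  periods <- diff(marks$times)
  amps <- marks$amps[-length(marks$amps)]
  tibble(
    jitt = mean(abs(diff(periods))) / mean(periods) * 100,
    shim = mean(abs(diff(amps))) / mean(amps) * 100,
    n_cycles_used = n_cyc
  )
}

#' Cepstral peak prominence and harmonics-to-noise ratio
#'
#' Both measures are computed per 40 ms Hann window (50% overlap) and
#' averaged over windows.
#'
#' CPP: the real cepstrum is taken as the power of the Fourier transform of
#' the dB log-power spectrum, expressed in dB; a regression line of
#' cepstrum magnitude on quefrency is fitted over the plausible voice band
#' (1/880 s to 1/60 s), and CPP is the height of the cepstral peak above
#' the regression value at the peak quefrency.
#'
#' HNR: the normalized autocorrelation of the Hann-windowed segment is
#' divided by the autocorrelation of the window itself; the maximum `r` at
#' the fundamental period gives `HNR = 10*log10(r / (1 - r))`, capped at
#' +40 dB.
#'
#' @inheritParams perturbation_indices
#' @param window_s Analysis window length in s (default 0.04).
#' @param overlap Window overlap fraction (default 0.5).
#' @param hnr_cap Upper cap for HNR in dB (default 40).
#' @return A one-row tibble with columns `CPP` (dB) and `HNR` (dB).
#' @export
quality_indices <- function(audio, fs = NULL, window_s = 0.04, overlap = 0.5,
                            hnr_cap = 40) {
  fs <- resolve_fs(audio, fs)
  x <- signal_values(audio, "amplitude")
  if (length(x) < 0.5 * fs) {
    phono_abort("Audio shorter than 0.5 s; cannot compute CPP/HNR.",
                class = "phonolab_error_format")
  }
  nw <- round(window_s * fs)
  hop <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, length(x) - nw + 1L, by = hop)
  f0 <- estimate_f0_acf(x, fs, min_peak = 0.3)$f0
  lag0 <- fs / f0

  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))
  nfft <- 2^ceiling(log2(2L * nw))
  q_lo <- ceiling(fs / 880)
  q_hi <- floor(fs / 60)
  q <- (q_lo:q_hi) / fs

  # window autocorrelation, for the Boersma normalisation
  hw_pad <- c(hann, numeric(nfft - nw))
  r_w <- Re(stats::fft(Mod(stats::fft(hw_pad))^2, inverse = TRUE))
  r_w <- r_w / r_w[1]

  cpp_vals <- numeric(0)
  hnr_vals <- numeric(0)
  for (s in starts) {
    seg <- x[s:(s + nw - 1L)]
    seg <- seg - mean(seg)
    segw <- seg * hann
    spec <- Mod(stats::fft(c(segw, numeric(nfft - nw))))^2
    log_spec <- 10 * log10(spec + 1e-300)
    cep <- 10 * log10(Mod(stats::fft(log_spec))^2 + 1e-300)
    band <- cep[(q_lo + 1L):(q_hi + 1L)]
    fitted <- stats::lm.fit(cbind(1, q), band)$fitted.values
    j <- which.max(band - fitted)
    cpp_vals <- c(cpp_vals, band[j] - fitted[j])

    r_x <- Re(stats::fft(Mod(stats::fft(c(segw, numeric(nfft - nw))))^2, inverse = TRUE))
    r_x <- r_x / r_x[1]
    lo <- max(2L, floor(0.8 * lag0))
    hi <- min(nw - 2L, ceiling(1.25 * lag0))
    rr <- r_x[seq_len(hi + 2L)] / r_w[seq_len(hi + 2L)]
    k <- lo + which.max(rr[(lo + 1L):(hi + 1L)]) - 1L
    pk <- parabolic_peak(rr[k], rr[k + 1L], rr[k + 2L])
    r <- min(max(pk$value, 1e-9), 1 - 1e-9)
    hnr_vals <- c(hnr_vals, min(hnr_cap, 10 * log10(r / (1 - r))))
  }
  tibble(CPP = mean(cpp_vals), HNR = mean(hnr_vals))
}

#' All acoustic and pressure-derived parameters of one measurement
#'
#' @param audio Audio signal tibble (`t`, `amplitude`).
#' @param pressure Pressure trace tibble (`t`, `p_pa`).
#' @param fs_audio,fs_pressure Sampling rates; inferred when `NULL`.
#' @param min_cycles Minimum cycles for jitter/shimmer (default 100).
#' @return A one-row tibble: `F0`, `Psub`, `CPP`, `HNR`, `jitt`, `shim`,
#'   `n_cycles_used`.
#' @export
acoustic_parameters <- function(audio, pressure, fs_audio = NULL,
                                fs_pressure = NULL, min_cycles = 100L) {
  dplyr::bind_cols(
    pressure_parameters(pressure, fs = fs_pressure),
    quality_indices(audio, fs = fs_audio),
    perturbation_indices(audio, fs = fs_audio, min_cycles = min_cycles)
  )
}
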