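#' Specify a synthetic vocal-fold oscillator
#'
#' An `oscillator_spec` holds the ground-truth parameters of one synthetic
#' phonation recording: the kinematics of the two vocal-fold medial edges
#' (rectified-sinusoid excursion plus a prephonatory half-gap), the
#' cycle-to-cycle perturbation targets, and the acoustic/aerodynamic targets.
#' All generators ([generate_gaw()], [generate_audio()],
#' [generate_pressure()], [render_frames()]) are deterministic given `seed`.
#'
#' The per-side open width at time t is
#' `w(t) = max(0, baseline_gap + amp * sin(phase))`, so the folds touch
#' (complete glottal closure) whenever the excursion amplitude reaches or
#' exceeds the half-gap; a `baseline_gap` larger than the amplitude leaves a
#' permanent glottal gap (incomplete closure). The hemiglottal area is
#' `glottal_length * w(t)`.
#'
#' Cycle-to-cycle perturbation uses independent lognormal multipliers on each
#' cycle's period and amplitude, calibrated in closed form so that the
#' expected *local* jitter/shimmer (mean absolute difference of successive
#' cycles over the mean) equals `jitter_pct` / `shimmer_pct`.
#'
#' @param f0 Fundamental frequency in Hz (> 0).
#' @param n_cycles Number of nominal oscillation cycles to generate. Use at
#'   least 20 for waveform analysis and at least 100 for acoustic
#'   perturbation analysis.
#' @param fs_video Video sampling rate in frames/s (default 4000).
#' @param fs_audio Audio/pressure sampling rate in samples/s (default 44100).
#' @param amp_left,amp_right Lateral half-amplitude of each fold's
#'   medial-edge excursion, in px (>= 0).
#' @param phase_offset_frac Delay of the right fold relative to the left, as
#'   a fraction of a period, in \[0, 0.5\].
#' @param baseline_gap Prephonatory half-gap in px (0 means the folds touch
#'   at maximum closure).
#' @param glottal_length Anterior-posterior glottal length in px (> 0).
#' @param jitter_pct,shimmer_pct Target local cycle-to-cycle period and
#'   amplitude perturbation, in percent (>= 0).
#' @param hnr_target Harmonic-to-noise power ratio of the generated audio in
#'   dB; `Inf` produces a noise-free signal.
#' @param psub_mean Mean subglottal pressure in Pa (>= 0).
#' @param seed Integer seed; mandatory source of all randomness.
#'
#' @return An object of class `oscillator_spec` (a named list).
#' @examples
#' spec <- oscillator_spec(f0 = 200, n_cycles = 40, seed = 1)
#' gaw <- generate_gaw(spec)
#' head(gaw)
#' @export
oscillator_spec <- function(f0 = 200,
                            n_cycles = 40,
                            fs_video = 4000,
                            fs_audio = 44100,
                            amp_left = 20,
                            amp_right = 20,
                            phase_offset_frac = 0,
                            baseline_gap = 0,
                            glottal_length = 240,
                            jitter_pct = 0,
                            shimmer_pct = 0,
                            hnr_target = Inf,
                            psub_mean = 1500,
                            seed = 1L) {
  check_number(f0, "f0", min = .Machine$double.eps)
  n_cycles <- check_count(n_cycles, "n_cycles", min = 1L)
  check_number(fs_video, "fs_video", min = .Machine$double.eps)
  check_number(fs_audio, "fs_audio", min = .Machine$double.eps)
  check_number(amp_left, "amp_left", min = 0)
  check_number(amp_right, "amp_right", min = 0)
  check_number(phase_offset_frac, "phase_offset_frac", min = 0, max = 0.5)
  check_number(baseline_gap, "baseline_gap", min = 0)
  check_number(glottal_length, "glottal_length", min = .Machine$double.eps)
  check_number(jitter_pct, "jitter_pct", min = 0)
  check_number(shimmer_pct, "shimmer_pct", min = 0)
  check_number(hnr_target, "hnr_target", allow_inf = TRUE)
  check_number(psub_mean, "psub_mean", min = 0)
  seed <- check_count(seed, "seed", min = 0L)
  structure(
    list(
      f0 = f0, n_cycles = n_cycles,
      fs_video = fs_video, fs_audio = fs_audio,
      amp_left = amp_left, amp_right = amp_right,
      phase_offset_frac = phase_offset_frac,
      baseline_gap = baseline_gap,
      glottal_length = glottal_length,
      jitter_pct = jitter_pct, shimmer_pct = shimmer_pct,
      hnr_target = hnr_target, psub_mean = psub_mean,
      seed = seed
    ),
    class = "oscillator_spec"
  )
}

#' @export
print.oscillator_spec <- function(x, ...) {
  cat("<oscillator_spec>\n")
  cat(sprintf("  f0: %g Hz, %d cycles (video %g fps, audio %g Hz)\n",
              x$f0, x$n_cycles, x$fs_video, x$fs_audio))
  cat(sprintf("  amplitudes L/R: %g/%g px, phase offset: %g of a period\n",
              x$amp_left, x$amp_right, x$phase_offset_frac))
  cat(sprintf("  half-gap: %g px, glottal length: %g px\n",
              x$baseline_gap, x$glottal_length))
  cat(sprintf("  jitter: %g%%, shimmer: %g%%, HNR target: %s dB, Psub: %g Pa\n",
              x$jitter_pct, x$shimmer_pct, format(x$hnr_target), x$psub_mean))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# --- cycle-to-cycle perturbation ------------------------------------------

# For X, Y iid lognormal(mu, sigma) with E[X] = 1, the local perturbation
# E|X - Y| / E[X] equals 2 * (2 * pnorm(sigma / sqrt(2)) - 1); inverting that
# gives the sigma that realizes a requested local jitter/shimmer in
# expectation.
lognormal_sigma_for_local_pct <- function(pct) {
  if (pct <= 0) return(0)
  sqrt(2) * stats::qnorm(0.5 + pct / 400)
}

cycle_multipliers <- function(n, pct) {
  sigma <- lognormal_sigma_for_local_pct(pct)
  if (sigma == 0) return(rep(1, n))
  exp(stats::rnorm(n, mean = -sigma^2 / 2, sd = sigma))
}

# Draw per-cycle periods and amplitude factors for a spec (RNG state is the
# caller's responsibility).
draw_cycles <- function(spec, n_cycles) {
  tibble(
    period = (1 / spec$f0) * cycle_multipliers(n_cycles, spec$jitter_pct),
    amp_factor = cycle_multipliers(n_cycles, spec$shimmer_pct)
  )
}

# Sample a piecewise-linear phase track: within cycle i the phase advances
# from phase0 + 2*pi*(i-1) to phase0 + 2*pi*i over period[i].
sample_phase <- function(periods, fs, phase0 = 0) {
  edges <- c(0, cumsum(periods))
  n <- floor(edges[length(edges)] * fs)
  t <- (seq_len(n) - 1L) / fs
  cyc <- findInterval(t, edges, rightmost.closed = FALSE)
  cyc[cyc > length(periods)] <- length(periods)
  frac <- (t - edges[cyc]) / periods[cyc]
  list(t = t, phase = phase0 + 2 * pi * (cyc - 1 + frac), cycle = cyc)
}

# Per-sample amplitude multiplier: constant at the cycle's lognormal factor
# except for a smooth cosine cross-fade to the next cycle's factor, of total
# width `w` (fraction of a period) centred at cycle fraction `center`. The
# fade is placed away from the waveform feature that carries the cycle's
# amplitude (the area peak / the acoustic pulse), so every cycle's measured
# amplitude equals its factor exactly and no step discontinuities exist.
amp_track <- function(ph, amp_factor, center = 0.8, w = 0.2) {
  cyc <- ph$cycle
  frac <- (ph$phase - ph$phase[1]) / (2 * pi) - (cyc - 1)
  n <- length(amp_factor)
  m <- amp_factor[cyc]
  nxt <- amp_factor[pmin(cyc + 1L, n)]
  mid <- frac >= center - w / 2 & frac <= center + w / 2
  if (any(mid)) {
    s <- 0.5 - 0.5 * cos(pi * (frac[mid] - center + w / 2) / w)
    m[mid] <- m[mid] + (nxt[mid] - m[mid]) * s
  }
  hi <- frac > center + w / 2
  m[hi] <- nxt[hi]
  m
}
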