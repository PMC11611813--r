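# Cycle-based waveform parameters: periodicity, symmetry, closure, and
# tissue-elasticity indices. All indices are arithmetic means over the
# analysed cycles; at least 20 cycles are required for a stable estimate.

check_min_cycles <- function(cycles, min_cycles) {
  if (nrow(cycles) < min_cycles) {
    phono_abort(
      sprintf("Only %d cycles available; at least %d are required.",
              nrow(cycles), min_cycles),
      class = "phonolab_error_insufficient_cycles", n_detected = nrow(cycles)
    )
  }
}

#' Amplitude and time periodicity (AP, TP)
#'
#' For each pair of consecutive cycles the ratio of the smaller to the
#' larger cycle amplitude respectively cycle duration is taken; AP and TP
#' are the means of these ratios. Both lie in \[0, 1\] with 1 meaning a
#' perfectly repeating oscillation. The amplitude used is the cycle's
#' oscillatory amplitude `a_osc` when available (its ratios track the true
#' cycle-to-cycle amplitude variation uniformly for closing and
#' non-closing oscillations), falling back to the peak-to-peak range.
#'
#' @param cycles A `cycle_df` from [detect_cycles()], or any tibble with
#'   `a_osc` (or `a_range`) and `duration` columns.
#' @param min_cycles Minimum number of cycles (default 20).
#' @return A one-row tibble with columns `AP` and `TP`.
#' @export
periodicity_indices <- function(cycles, min_cycles = 20L) {
  check_min_cycles(cycles, min_cycles)
  a <- if ("a_osc" %in% names(cycles)) cycles$a_osc else cycles$a_range
  if (any(a <= 0)) {
    phono_abort(
      sprintf("Cycle %d has zero amplitude; periodicity is undefined.",
              which(a <= 0)[1]),
      class = "phonolab_error_degenerate", cycle = which(a <= 0)[1]
    )
  }
  d <- cycles$duration
  pair_ratio <- function(v) mean(pmin(v[-length(v)], v[-1]) / pmax(v[-length(v)], v[-1]))
  tibble(AP = pair_ratio(a), TP = pair_ratio(d))
}

#' Left/right symmetry indices (ASI, PAI)
#'
#' ASI is the mean over cycles of the smaller-to-larger ratio of the left
#' and right hemiglottal cycle amplitudes (1 = symmetric), using the
#' oscillatory amplitudes `a_osc_*` when available. PAI is the mean
#' over cycles of the absolute left-right peak-time lag normalised by the
#' cycle duration, clipped to \[0, 1\] (0 = symmetric).
#'
#' @inheritParams periodicity_indices
#' @return A one-row tibble with columns `ASI` and `PAI`.
#' @export
symmetry_indices <- function(cycles, min_cycles = 20L) {
  check_min_cycles(cycles, min_cycles)
  need <- c("a_range_left", "a_range_right", "t_peak_left", "t_peak_right")
  if (!all(need %in% names(cycles))) {
    phono_abort("Left/right hemiglottal series are required for symmetry indices.",
                class = "phonolab_error_format")
  }
  if (all(c("a_osc_left", "a_osc_right") %in% names(cycles))) {
    al <- cycles$a_osc_left; ar <- cycles$a_osc_right
  } else {
    al <- cycles$a_range_left; ar <- cycles$a_range_right
  }
  if (all(al <= 0) || all(ar <= 0)) {
    phono_abort("One side never oscillates; symmetry indices are undefined.",
                class = "phonolab_error_one_sided")
  }
  asi <- mean(pmin(al, ar) / pmax(al, ar))
  pai <- mean(pmin(1, abs(cycles$t_peak_left - cycles$t_peak_right) / cycles$duration))
  tibble(ASI = asi, PAI = pai)
}

#' Glottal closure indices (GGI, ClQ, MADR)
#'
#' GGI is the mean over cycles of the minimum-to-maximum area ratio
#' (0 = complete closure, 1 = no modulation). ClQ under the default
#' `"closing_quotient"` reading is the mean normalised time from the cycle
#' peak to the following area minimum (0.5 for a symmetric oscillation);
#' the alternative `"closed_phase"` reading is the mean fraction of the
#' cycle spent with the area at or below `closed_epsilon` times the cycle
#' maximum (set via [detect_cycles()]). MADR is the mean over cycles of the
#' steepest area decline during closing, reported as a positive magnitude
#' in Mpx/s.
#'
#' @inheritParams periodicity_indices
#' @param clq_method `"closing_quotient"` (default) or `"closed_phase"`.
#' @param pixel_scale Area units per px^2 used for MADR; the default 1e-6
#'   reports MADR in Mpx/s from areas measured in px^2.
#' @return A one-row tibble with columns `GGI`, `ClQ`, `MADR`.
#' @export
closure_indices <- function(cycles, clq_method = c("closing_quotient", "closed_phase"),
                            pixel_scale = 1e-6, min_cycles = 20L) {
  check_min_cycles(cycles, min_cycles)
  clq_method <- match.arg(clq_method)
  ggi <- mean(pmax(0, cycles$a_min) / cycles$a_max)
  clq <- if (clq_method == "closing_quotient") {
    mean((cycles$t_min_after_peak - cycles$t_peak) / cycles$duration)
  } else {
    mean(cycles$closed_frac)
  }
  madr <- mean(cycles$closing_rate_max) * pixel_scale
  tibble(GGI = ggi, ClQ = min(1, max(0, clq)), MADR = madr)
}

#' Tissue-elasticity indices (stiff, ALR)
#'
#' The stiffness parameter is the mean over cycles of the cycle maximum of
#' `s(t) = |dA/dt|` divided by the cycle's dynamic range (units 1/s): the
#' maximum opening/closing speed of the glottis relative to how far it
#' opens. For a pure sinusoid this equals `pi * f0`. ALR is the mean over
#' cycles of the cycle amplitude divided by twice the squared glottal
#' length — the lateral oscillation amplitude normalised by the glottal
#' length (dimensionless, lower = stiffer).
#'
#' @inheritParams periodicity_indices
#' @param length_px Constant glottal length in px, used if the waveform
#'   carried no length series.
#' @return A one-row tibble with columns `stiff` and `ALR`. A missing
#'   glottal length raises an error of class
#'   `phonolab_error_alr_unavailable` that carries the already-computed
#'   `stiff` value as a condition field.
#' @export
elasticity_indices <- function(cycles, length_px = NULL, min_cycles = 20L) {
  check_min_cycles(cycles, min_cycles)
  if (any(cycles$a_range <= 0)) {
    phono_abort("A cycle has zero dynamic range; stiffness is undefined.",
                class = "phonolab_error_degenerate")
  }
  stiff <- mean(cycles$s_max / cycles$a_range)
  len <- if ("length_mean" %in% names(cycles)) cycles$length_mean else length_px
  if (is.null(len)) {
    phono_abort("No glottal-length series and no `length_px` supplied; ALR is unavailable (stiff alone can be computed via `stiff = mean(s_max / a_range)`).",
                class = "phonolab_error_alr_unavailable", stiff = stiff)
  }
  alr <- mean(cycles$a_range / (2 * len^2))
  tibble(stiff = stiff, ALR = alr)
}

#' All waveform-derived parameters of one measurement
#'
#' Convenience wrapper: runs [detect_cycles()] and assembles the nine
#' waveform parameters (AP, TP, ASI, PAI, GGI, ClQ, MADR, stiff, ALR) into
#' a single row.
#'
#' @inheritParams detect_cycles
#' @inheritParams closure_indices
#' @inheritParams elasticity_indices
#' @return A one-row tibble with the nine parameters plus `n_cycles_used`.
#' @examples
#' gaw <- generate_gaw(oscillator_spec(f0 = 200, n_cycles = 40, seed = 2))
#' gaw_parameters(gaw)
#' @export
gaw_parameters <- function(gaw, fs = NULL, f0 = NULL,
                           clq_method = c("closing_quotient", "closed_phase"),
                           pixel_scale = 1e-6, length_px = NULL,
                           min_cycles = 20L, closed_epsilon = 0.02) {
  cycles <- detect_cycles(gaw, fs = fs, f0 = f0, min_cycles = min_cycles,
                          closed_epsilon = closed_epsilon)
  sym <- if (all(c("t_peak_left", "t_peak_right") %in% names(cycles))) {
    symmetry_indices(cycles, min_cycles)
  } else {
    tibble(ASI = NA_real_, PAI = NA_real_)   # no left/right split available
  }
  dplyr::bind_cols(
    periodicity_indices(cycles, min_cycles),
    sym,
    closure_indices(cycles, clq_method = clq_method, pixel_scale = pixel_scale,
                    min_cycles = min_cycles),
    elasticity_indices(cycles, length_px = length_px, min_cycles = min_cycles),
    tibble(n_cycles_used = nrow(cycles))
  )
}
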