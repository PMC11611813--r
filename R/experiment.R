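# The two-factor (flow rate x fiber stretching length) experiment grid and
# the condition -> oscillator response model.

flow_group_values <- list(
  FG1 = c(30, 32, 34, 36, 38, 40),
  FG2 = c(50, 60, 70, 80),
  FG3 = c(90, 100, 110, 120),
  FG4 = c(130, 140, 150, 160, 170, 180, 190, 200)
)

#' Default two-factor experiment grid
#'
#' 76 (flow, stretch) conditions whose flow values are drawn from the four
#' canonical flow-group value sets with per-group counts 18, 18, 20, 20,
#' spread over the five stretching lengths 0, 5, 10, 15, 20 mm. The exact
#' pairing is a package default chosen so that (a) the onset flow is
#' non-decreasing with stretch, mirroring the measurement protocol in which
#' higher-tension states start oscillating at higher flows, and (b) the
#' mean flow per stretch level stays approximately balanced, so the grid
#' itself induces no artificial stretch-to-pressure confound.
#'
#' @return A tibble with columns `id`, `flow` (SLM) and `stretch` (mm).
#' @examples
#' nrow(default_experiment_grid())  # 76
#' @export
default_experiment_grid <- function() {
  per_level <- list(
    `0`  = c(30, 32, 34, 36, 38, 50, 60, 70, 80, 90, 100, 110, 120, 170, 180, 190, 200),
    `5`  = c(32, 34, 36, 40, 50, 60, 70, 80, 90, 100, 110, 120, 170, 180, 190, 200),
    `10` = c(34, 36, 38, 40, 50, 60, 70, 80, 90, 100, 110, 120, 170, 180, 190, 200),
    `15` = c(36, 38, 40, 60, 70, 80, 90, 100, 110, 120, 130, 140, 150, 160),
    `20` = c(38, 40, 60, 70, 80, 90, 100, 110, 120, 130, 140, 150, 160)
  )
  grid <- dplyr::bind_rows(lapply(names(per_level), function(s) {
    tibble(flow = per_level[[s]], stretch = as.numeric(s))
  }))
  grid <- dplyr::arrange(grid, .data$stretch, .data$flow)
  dplyr::mutate(grid, id = dplyr::row_number(), .before = 1)
}

#' Default condition-response coefficients
#'
#' The mapping from a (flow, stretch) condition to the oscillator spec.
#' The encoded responses mirror the qualitative findings the simulator is
#' meant to reproduce: subglottal pressure rises linearly with flow;
#' oscillation amplitude rises with flow and saturates; F0 rises with
#' stretch and saturates above `sat_mm` (10 mm); the prephonatory gap
#' closes with stretch (complete closure from `sat_mm` on); acoustic
#' harmonicity improves with both flow and stretch; jitter/shimmer decline
#' mildly with stretch; and an amplitude-instability band inflates shimmer
#' for mid-range flows only.
#'
#' @return A named list of coefficients; override entries via the
#'   `coefficients` argument of [simulate_experiment()].
#' @export
default_response_coefficients <- function() {
  list(
    psub_intercept = 200, psub_slope = 14,         # Pa, Pa/SLM
    amp_max = 40, amp_flow_half = 60,              # px, SLM
    amp_right_ratio = 0.94,                        # fixed left/right asymmetry
    phase_offset_frac = 0.02,                      # fixed phase lag (fraction of T)
    f0_base = 220, f0_span = 120, sat_mm = 10,     # Hz, Hz, mm
    gap0 = 90,                                     # px at stretch 0
    glottal_length = 240,                          # px
    hnr_base = 8, hnr_flow = 2.5, hnr_stretch = 8, # dB
    jitter_base = 1.5, jitter_drop = 0.15,         # %
    shimmer_base = 1.9, shimmer_drop = 0.1,        # %
    instability_flow = c(45, 85),                  # SLM band with amplitude instability
    instability_factor = c(1.3, 2.3),              # shimmer multiplier range in that band
    f0_cv = 0.02, amp_cv = 0.05,                   # condition-to-condition noise
    hnr_sd = 1.2, perturb_cv = 0.7,
    asym_cv = 0.03, phase_cv = 0.2,                # asymmetry variability across conditions
    n_cycles_gaw = 40, audio_seconds = 1
  )
}

# Ground-truth oscillator spec for one condition. RNG must be seeded by the
# caller; draws only condition-level variability.
condition_spec <- function(flow, stretch, seed, co) {
  sat <- min(stretch, co$sat_mm) / co$sat_mm
  f0 <- (co$f0_base + co$f0_span * sat) * exp(stats::rnorm(1, sd = co$f0_cv))
  amp <- co$amp_max * flow / (flow + co$amp_flow_half) * exp(stats::rnorm(1, sd = co$amp_cv))
  gap <- co$gap0 * max(0, 1 - stretch / co$sat_mm)
  jitter <- (co$jitter_base - co$jitter_drop * sat) * exp(stats::rnorm(1, sd = co$perturb_cv))
  shimmer <- (co$shimmer_base - co$shimmer_drop * sat) * exp(stats::rnorm(1, sd = co$perturb_cv))
  if (flow >= co$instability_flow[1] && flow <= co$instability_flow[2]) {
    shimmer <- shimmer * stats::runif(1, co$instability_factor[1], co$instability_factor[2])
  }
  hnr <- co$hnr_base + co$hnr_flow * log(flow / 30) + co$hnr_stretch * sat +
    stats::rnorm(1, sd = co$hnr_sd)
  ratio <- min(1, co$amp_right_ratio * exp(stats::rnorm(1, sd = co$asym_cv)))
  phase <- min(0.5, co$phase_offset_frac * exp(stats::rnorm(1, sd = co$phase_cv)))
  oscillator_spec(
    f0 = f0,
    n_cycles = co$n_cycles_gaw,
    amp_left = amp,
    amp_right = amp * ratio,
    phase_offset_frac = phase,
    baseline_gap = gap,
    glottal_length = co$glottal_length,
    jitter_pct = jitter,
    shimmer_pct = shimmer,
    hnr_target = hnr,
    psub_mean = co$psub_intercept + co$psub_slope * flow,
    seed = seed
  )
}

#' Simulate the full two-factor experiment
#'
#' Generates one synthetic recording bundle (glottal area waveform, audio,
#' pressure trace, ground truth) per condition of the grid. Deterministic
#' given `seed`; every condition gets its own derived seed so bundles are
#' independent but reproducible.
#'
#' @param grid A condition tibble with columns `flow` (SLM) and `stretch`
#'   (mm); defaults to [default_experiment_grid()].
#' @param seed Integer master seed.
#' @param coefficients Named list overriding entries of
#'   [default_response_coefficients()].
#' @return A nested tibble with one row per condition: `id`, `flow`,
#'   `stretch`, list-columns `spec`, `gaw`, `audio`, `pressure`, and the
#'   ground-truth columns `f0_target`, `psub_target`, `asi_target`,
#'   `pai_target`, `jitter_target`, `shimmer_target`, `hnr_target`,
#'   `gap_px`, `amp_left_px`, `amp_right_px`.
#' @examples
#' \donttest{
#' sim <- simulate_experiment(default_experiment_grid()[1:2, ], seed = 1)
#' sim$f0_target
#' }
#' @export
simulate_experiment <- function(grid = default_experiment_grid(), seed = 1L,
                                coefficients = list()) {
  if (!is.data.frame(grid) || nrow(grid) == 0L ||
      !all(c("flow", "stretch") %in% names(grid))) {
    phono_abort("`grid` must be a non-empty data frame with `flow` and `stretch` columns.",
                class = "phonolab_error_validation")
  }
  seed <- check_count(seed, "seed", min = 0L)
  co <- utils::modifyList(default_response_coefficients(), coefficients)
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    cond_seed <- (seed + 97L * i) %% .Machine$integer.max
    spec <- withr::with_seed(cond_seed,
                             condition_spec(grid$flow[i], grid$stretch[i], cond_seed, co))
    gaw <- generate_gaw(spec, n_cycles = co$n_cycles_gaw)
    audio <- generate_audio(spec, n_cycles = ceiling(co$audio_seconds * spec$f0))
    pressure <- generate_pressure(spec, duration = co$audio_seconds)
    truth <- tibble(
      f0_target = spec$f0,
      psub_target = spec$psub_mean,
      asi_target = min(spec$amp_left, spec$amp_right) /
        max(spec$amp_left, spec$amp_right),
      pai_target = spec$phase_offset_frac,
      jitter_target = spec$jitter_pct,
      shimmer_target = spec$shimmer_pct,
      hnr_target = spec$hnr_target,
      gap_px = spec$baseline_gap,
      amp_left_px = spec$amp_left, amp_right_px = spec$amp_right
    )
    dplyr::bind_cols(
      tibble(
        id = if ("id" %in% names(grid)) grid$id[i] else i,
        flow = grid$flow[i], stretch = grid$stretch[i],
        spec = list(spec), gaw = list(gaw), audio = list(audio),
        pressure = list(pressure)
      ),
      truth
    )
  })
  purrr::list_rbind(rows)
}
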