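# End-to-end orchestration: simulate -> analyse each recording -> assemble
# the measurement table -> run both grouped significance reports.

#' Analyse every recording of a simulated experiment
#'
#' Runs the waveform analysis ([gaw_parameters()]) and the
#' acoustic/pressure analysis ([acoustic_parameters()]) on every condition
#' of a [simulate_experiment()] result and assembles one row per
#' measurement: the condition labels plus the fifteen phonation
#' parameters.
#'
#' @param sim A nested tibble from [simulate_experiment()].
#' @param use_frames If `TRUE`, each waveform is re-derived by rendering a
#'   synthetic frame stack and segmenting it back (slow; exercises the
#'   imaging path). Default `FALSE`: the generated waveform is analysed
#'   directly.
#' @param frame_dims Frame size for `use_frames = TRUE`.
#' @param min_cycles_audio Minimum audio cycles for jitter/shimmer
#'   (default 100).
#' @return A tibble with columns `flow`, `stretch` and
#'   [phonation_parameters()] (17 columns), one row per condition. Failed
#'   conditions keep their row with `NA` parameters and are reported in a
#'   `phonolab_warning_condition_failed` warning.
#' @export
phonation_table <- function(sim, use_frames = FALSE, frame_dims = c(256L, 256L),
                            min_cycles_audio = 100L) {
  stopifnot(is.data.frame(sim), all(c("gaw", "audio", "pressure") %in% names(sim)))
  rows <- purrr::map(seq_len(nrow(sim)), function(i) {
    cond <- tibble(flow = sim$flow[i], stretch = sim$stretch[i])
    res <- tryCatch({
      gaw <- sim$gaw[[i]]
      if (use_frames) {
        frames <- render_frames(gaw, sim$spec[[i]], dims = frame_dims)
        gaw <- segment_frames(frames, fs_video = sim$spec[[i]]$fs_video)
      }
      gp <- gaw_parameters(gaw)
      ap <- acoustic_parameters(sim$audio[[i]], sim$pressure[[i]],
                                min_cycles = min_cycles_audio)
      dplyr::bind_cols(cond, ap[c("F0", "Psub")],
                       gp[c("AP", "TP", "ASI", "PAI", "GGI", "ClQ", "MADR",
                            "stiff", "ALR")],
                       ap[c("CPP", "HNR", "jitt", "shim")])
    }, phonolab_error = function(e) {
      rlang::warn(sprintf("Condition %d (flow %g, stretch %g) failed: %s",
                          i, cond$flow, cond$stretch, conditionMessage(e)),
                  class = "phonolab_warning_condition_failed")
      na <- as.list(rep(NA_real_, length(phonation_parameters())))
      names(na) <- phonation_parameters()
      dplyr::bind_cols(cond, as_tibble(na))
    })
    res
  })
  purrr::list_rbind(rows)
}

#' Run the complete simulation-and-analysis pipeline
#'
#' Simulates the experiment grid, analyses every recording, and computes
#' both grouped significance reports (flow design and stretch design).
#' Fully deterministic given `seed`: running twice with the same arguments
#' yields identical tables and reports.
#'
#' @inheritParams simulate_experiment
#' @inheritParams phonation_table
#' @param out_dir Optional directory; when given, the measurement table and
#'   both reports are written there as CSV/JSON together with a manifest.
#' @return An object of class `phonation_run`: a list with `table` (the
#'   measurement tibble), `report_flow`, `report_stretch`, and `manifest`
#'   (seed, grid size, coefficients).
#' @examples
#' \donttest{
#' run <- run_phonation_pipeline(seed = 1)
#' glance(run$report_flow)
#' }
#' @export
run_phonation_pipeline <- function(grid = default_experiment_grid(), seed = 1L,
                                   coefficients = list(), use_frames = FALSE,
                                   out_dir = NULL) {
  sim <- simulate_experiment(grid, seed = seed, coefficients = coefficients)
  tab <- phonation_table(sim, use_frames = use_frames)
  run <- structure(
    list(
      table = tab,
      report_flow = significance_report(tab, design = "flow"),
      report_stretch = significance_report(tab, design = "stretch"),
      manifest = list(
        seed = seed,
        n_conditions = nrow(tab),
        n_failed = sum(!stats::complete.cases(tab)),
        use_frames = use_frames,
        coefficients = utils::modifyList(default_response_coefficients(), coefficients)
      )
    ),
    class = "phonation_run"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_parameter_table(tab, file.path(out_dir, "parameters.csv"))
    write_report(run$report_flow, file.path(out_dir, "report_flow"))
    write_report(run$report_stretch, file.path(out_dir, "report_stretch"))
    jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run
}

#' @export
print.phonation_run <- function(x, ...) {
  cat(sprintf("<phonation_run: %d measurements (%d failed), seed %d>\n",
              x$manifest$n_conditions, x$manifest$n_failed, x$manifest$seed))
  cat("Flow design:\n")
  print(glance(x$report_flow))
  cat("Stretch design:\n")
  print(glance(x$report_stretch))
  invisible(x)
}
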