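#' Detect oscillation cycles in a glottal area waveform
#'
#' The fundamental frequency is pre-estimated from the normalized
#' autocorrelation of the mean-removed total area. The series is lightly
#' smoothed (Savitzky-Golay, order 3, window of about one tenth of a
#' period), cycle boundaries are placed at the local minima between
#' successive upward crossings of the 50%-of-dynamic-range level, and all
#' per-cycle quantities (durations, dynamic ranges, peak times, extrema,
#' derivative maxima) are measured on a dense cubic-spline interpolant so
#' they do not inherit the video frame quantisation.
#'
#' @param gaw A `gaw_df` or data frame with columns `t` and `area_total`
#'   (optionally `area_left`, `area_right`, `length`).
#' @param fs Video sampling rate; inferred from `gaw` when `NULL`.
#' @param f0 Optional known fundamental frequency (Hz); skips the
#'   autocorrelation pre-estimate.
#' @param min_cycles Minimum number of detected cycles required (default 20,
#'   the floor used for stable waveform parameters).
#' @param oversample Dense-grid oversampling factor relative to the frame
#'   rate (default 16).
#' @param closed_epsilon Fraction of the cycle maximum below which the
#'   glottis counts as closed for the closed-phase quotient (default 0.02).
#' @return A tibble of class `cycle_df`, one row per cycle, with columns
#'   `cycle`, `t_start`, `t_end`, `duration`, `a_min`, `a_max`, `a_range`
#'   (peak-to-peak dynamic range), `a_osc` (oscillatory amplitude
#'   `2 * (peak - cycle mean)`, insensitive to trough-depth coupling
#'   between neighbouring cycles), `t_peak`, `s_max` (max |dA/dt|),
#'   `closing_rate_max` (max -dA/dt after the peak), `t_min_after_peak`,
#'   `closed_frac`, and, when left/right series are present,
#'   `a_range_left`, `a_range_right`, `a_osc_left`, `a_osc_right`,
#'   `t_peak_left`, `t_peak_right`; plus `length_mean` when a length
#'   series is present. Attributes: `fs`, `f0_estimate`.
#' @export
detect_cycles <- function(gaw, fs = NULL, f0 = NULL, min_cycles = 20L,
                          oversample = 16L, closed_epsilon = 0.02) {
  fs <- resolve_fs(gaw, fs)
  x <- signal_values(gaw, "area_total")
  n <- length(x)
  if (n < 16L) {
    phono_abort("Waveform too short for cycle detection.", class = "phonolab_error_format")
  }
  rng <- diff(range(x))
  if (rng <= 0) {
    phono_abort("Waveform has zero dynamic range; no oscillation to segment.",
                class = "phonolab_error_no_oscillation")
  }
  if (is.null(f0)) f0 <- estimate_f0_acf(x, fs)$f0

  win <- odd_at_least(fs / (10 * f0), lo = 5L)
  smooth <- function(v) {
    if (win >= length(v)) return(v)
    as.numeric(signal::sgolayfilt(v, p = 3, n = win))
  }
  xs <- smooth(x)

  level <- min(xs) + 0.5 * (max(xs) - min(xs))
  up <- which(xs[-n] < level & xs[-1] >= level)
  if (length(up) < 3L) {
    phono_abort("Fewer than two level crossings; no usable oscillation found.",
                class = "phonolab_error_no_oscillation")
  }
  # de-chatter: keep crossings at least half a nominal period apart
  keep <- up[1]
  for (u in up[-1]) {
    if (u - keep[length(keep)] >= 0.5 * fs / f0) keep <- c(keep, u)
  }
  if (length(keep) < 3L) {
    phono_abort("Fewer than two oscillation cycles detected.",
                class = "phonolab_error_insufficient_cycles", n_detected = 0L)
  }
  # Boundary = centre of the near-minimum region between crossings; for a
  # sharp trough this is the minimum itself, for a flat closed phase it is
  # the midpoint of the closed phase (stable against smoothing ripple).
  # A sub-frame boundary position is also computed on a dense spline so
  # cycle durations do not inherit the video frame quantisation.
  rng_s <- diff(range(xs))
  sf0 <- stats::splinefun(seq_len(length(xs)), xs, method = "fmm")
  bounds <- integer(length(keep) - 1L)
  bounds_t <- numeric(length(keep) - 1L)
  dstep <- 1 / 8
  for (k in seq_len(length(keep) - 1L)) {
    seg <- keep[k]:keep[k + 1L]
    dense <- seq(seg[1], seg[length(seg)], by = dstep)
    v <- sf0(dense)
    thr <- min(v) + 0.02 * rng_s
    near <- which(v <= thr)
    i1 <- near[1]; i2 <- near[length(near)]
    if (i1 > 1L && i2 < length(v)) {
      # centre of the trough, timed from the two threshold crossings: for a
      # flat closed phase this is its midpoint, for a sharp trough the
      # symmetric centre — both far more stable than the argmin
      t_down <- dense[i1 - 1L] +
        dstep * (v[i1 - 1L] - thr) / max(v[i1 - 1L] - v[i1], .Machine$double.eps)
      t_up <- dense[i2] +
        dstep * (thr - v[i2]) / max(v[i2 + 1L] - v[i2], .Machine$double.eps)
      bounds_t[k] <- (t_down + t_up) / 2
    } else {
      j <- which.min(v)
      if (j > 1L && j < length(v)) {
        pk <- parabolic_peak(-v[j - 1L], -v[j], -v[j + 1L])
        bounds_t[k] <- dense[j] + pk$offset * dstep
      } else {
        bounds_t[k] <- dense[j]
      }
    }
    bounds[k] <- seg[which.min(abs(seg - bounds_t[k]))]
  }
  n_cyc <- length(bounds) - 1L
  if (n_cyc < min_cycles) {
    phono_abort(
      sprintf("Only %d cycles detected; at least %d are required.", n_cyc, min_cycles),
      class = "phonolab_error_insufficient_cycles", n_detected = n_cyc
    )
  }

  t0 <- if (is.data.frame(gaw) && "t" %in% names(gaw)) gaw$t[1] else 0
  sf <- sf0
  has_sides <- is.data.frame(gaw) &&
    all(c("area_left", "area_right") %in% names(gaw))
  if (has_sides) {
    sfl <- stats::splinefun(seq_len(n), smooth(gaw$area_left), method = "fmm")
    sfr <- stats::splinefun(seq_len(n), smooth(gaw$area_right), method = "fmm")
  }
  has_len <- is.data.frame(gaw) && "length" %in% names(gaw)

  step <- 1 / oversample
  idx_time <- function(i) t0 + (i - 1) / fs

  peak_on <- function(fun, grid) {
    v <- fun(grid)
    j <- which.max(v)
    if (j == 1L || j == length(v)) return(list(t = grid[j], value = v[j]))
    pk <- parabolic_peak(v[j - 1L], v[j], v[j + 1L])
    list(t = grid[j] + pk$offset * step, value = pk$value)
  }

  rows <- vector("list", n_cyc)
  for (i in seq_len(n_cyc)) {
    b0 <- bounds[i]; b1 <- bounds[i + 1L]
    grid <- seq(bounds_t[i], bounds_t[i + 1L], by = step)
    a <- sf(grid)
    da <- sf(grid, deriv = 1) * fs
    j_max <- which.max(a)
    pk <- peak_on(sf, grid)
    a_max <- pk$value
    a_min <- max(0, min(a))   # areas are non-negative; spline ringing at
                              # closure corners must not push the range down
    after <- j_max:length(grid)
    j_min_after <- after[which.min(a[after])]    # earliest minimum on ties
    # oscillatory amplitude: peak height above the cycle's own starting
    # trough — a single-cycle quantity whose cycle-to-cycle ratios track the
    # true amplitude perturbation uniformly for closing and non-closing
    # oscillations (the peak-to-peak range mixes in the deeper of the two
    # flanking troughs)
    row <- tibble(
      cycle = i,
      t_start = idx_time(bounds_t[i]), t_end = idx_time(bounds_t[i + 1L]),
      duration = (bounds_t[i + 1L] - bounds_t[i]) / fs,
      a_min = a_min, a_max = a_max, a_range = a_max - a_min,
      a_osc = a_max - max(0, sf(bounds_t[i])),
      t_peak = idx_time(pk$t),
      s_max = max(abs(da)),
      closing_rate_max = max(-da[after]),
      t_min_after_peak = idx_time(grid[j_min_after]),
      closed_frac = mean(a <= closed_epsilon * a_max)
    )
    if (has_sides) {
      al <- sfl(grid); ar <- sfr(grid)
      pl <- peak_on(sfl, grid); pr <- peak_on(sfr, grid)
      row$a_range_left <- max(al) - min(al)
      row$a_range_right <- max(ar) - min(ar)
      row$a_osc_left <- pl$value - max(0, sfl(bounds_t[i]))
      row$a_osc_right <- pr$value - max(0, sfr(bounds_t[i]))
      row$t_peak_left <- idx_time(pl$t)
      row$t_peak_right <- idx_time(pr$t)
    }
    if (has_len) row$length_mean <- mean(gaw$length[b0:b1])
    rows[[i]] <- row
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "fs") <- fs
  attr(out, "f0_estimate") <- f0
  class(out) <- c("cycle_df", class(out))
  out
}
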