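# Internal helpers shared across modules.

phono_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "phonolab_error"), ...)
}

# Scalar numeric validator; every user-facing spec field funnels through this
# so errors always name the offending field.
check_number <- function(x, field, min = -Inf, max = Inf, allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x)
  if (ok && !allow_inf && !is.finite(x)) ok <- FALSE
  if (ok && is.infinite(x)) ok <- x > 0
  if (ok && is.finite(x)) ok <- x >= min && x <= max
  if (!ok) {
    phono_abort(
      sprintf(
        "Field `%s` must be a single finite number in [%s, %s]%s (got: %s).",
        field, format(min), format(max),
        if (allow_inf) " or +Inf" else "",
        paste(format(x), collapse = ", ")
      ),
      class = "phonolab_error_validation", field = field
    )
  }
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  check_number(x, field, min = min)
  if (x != round(x)) {
    phono_abort(sprintf("Field `%s` must be an integer (got %s).", field, format(x)),
                class = "phonolab_error_validation", field = field)
  }
  invisible(as.integer(x))
}

# Sampling rate of a uniformly sampled signal tibble: explicit argument wins,
# then an `fs` attribute, then the median time step.
resolve_fs <- function(x, fs = NULL) {
  if (!is.null(fs)) return(fs)
  a <- attr(x, "fs", exact = TRUE)
  if (!is.null(a)) return(a)
  if (is.data.frame(x) && "t" %in% names(x) && nrow(x) >= 2L) {
    return(1 / stats::median(diff(x$t)))
  }
  phono_abort("Cannot determine the sampling rate: supply `fs` or a `t` column.",
              class = "phonolab_error_format")
}

signal_values <- function(x, value_col) {
  if (is.data.frame(x)) {
    if (!value_col %in% names(x)) {
      phono_abort(sprintf("Column `%s` is missing from the signal table.", value_col),
                  class = "phonolab_error_format", column = value_col)
    }
    return(x[[value_col]])
  }
  as.numeric(x)
}

odd_at_least <- function(w, lo = 5L) {
  w <- max(as.integer(lo), as.integer(round(w)))
  if (w %% 2L == 0L) w <- w + 1L
  w
}

# Parabolic refinement of an extremum given three equally spaced samples
# (y1, y2, y3) around the discrete extremum at offset 0; returns the
# fractional offset in [-0.5, 0.5] and the interpolated value.
parabolic_peak <- function(y1, y2, y3) {
  denom <- y1 - 2 * y2 + y3
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps) {
    return(list(offset = 0, value = y2))
  }
  d <- 0.5 * (y1 - y3) / denom
  d <- max(-0.5, min(0.5, d))
  list(offset = d, value = y2 - 0.25 * (y1 - y3) * d)
}

# Normalized autocorrelation peak within a period band; the workhorse behind
# every fundamental-frequency estimate in the package.
estimate_f0_acf <- function(x, fs, fmin = 60, fmax = 880, min_peak = NULL) {
  x <- x - mean(x)
  n <- length(x)
  if (n < 8L || stats::sd(x) == 0) {
    phono_abort("Signal is constant; no oscillation to analyse.",
                class = "phonolab_error_no_oscillation")
  }
  nfft <- 2^ceiling(log2(2L * n))
  sp <- Mod(stats::fft(c(x, numeric(nfft - n))))^2
  ac <- Re(stats::fft(sp, inverse = TRUE))[seq_len(n)]
  ac <- ac / ac[1]
  lo <- max(2L, floor(fs / fmax))
  hi <- min(n - 2L, ceiling(fs / fmin))
  if (hi <= lo + 1L) {
    phono_abort("Signal too short for the configured F0 search band.",
                class = "phonolab_error_format")
  }
  band <- ac[(lo + 1L):(hi + 1L)]     # ac[k + 1] is lag k
  k <- lo + which.max(band) - 1L
  # octave guard: prefer the smallest lag whose local maximum comes close to
  # the global band maximum (subharmonic lags otherwise win on signals with
  # strong cycle-to-cycle amplitude variation)
  r_best <- max(band)
  loc_max <- which(diff(sign(diff(band))) == -2L) + 1L
  cand <- loc_max[band[loc_max] >= 0.9 * r_best]
  if (length(cand) > 0L) k <- lo + min(cand) - 1L
  pk <- parabolic_peak(ac[k], ac[k + 1L], ac[k + 2L])
  lag <- k + pk$offset
  peak_value <- pk$value
  if (!is.null(min_peak) && peak_value < min_peak) {
    phono_abort(
      sprintf("No autocorrelation peak above %.2f in the %g-%g Hz band (best: %.3f); signal looks unvoiced.",
              min_peak, fmin, fmax, peak_value),
      class = "phonolab_error_unvoiced", peak = peak_value
    )
  }
  list(f0 = fs / lag, lag = lag, peak = peak_value)
}
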