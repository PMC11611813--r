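# Plain-text and WAV readers/writers for every intermediate artifact, so
# each pipeline stage can be run and inspected independently. Column names
# embed the units.

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    phono_abort(sprintf("%s is missing required column(s): %s.",
                        what, paste(miss, collapse = ", ")),
                class = "phonolab_error_format", columns = miss)
  }
  invisible(df)
}

#' Read and write glottal area waveforms as CSV
#'
#' Dialect: columns `t_s`, `area_total_px2`, `area_left_px2`,
#' `area_right_px2`, `length_px`.
#'
#' @param gaw A `gaw_df`.
#' @param path File path.
#' @return `read_gaw_csv()` returns a `gaw_df`; `write_gaw_csv()` returns
#'   `path` invisibly.
#' @export
write_gaw_csv <- function(gaw, path) {
  out <- tibble(
    t_s = gaw$t, area_total_px2 = gaw$area_total,
    area_left_px2 = gaw$area_left, area_right_px2 = gaw$area_right,
    length_px = if ("length" %in% names(gaw)) gaw$length else NA_real_
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_gaw_csv
#' @export
read_gaw_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(df, c("t_s", "area_total_px2", "area_left_px2",
                        "area_right_px2"), "GAW CSV")
  new_gaw(
    tibble(
      t = df$t_s, area_total = df$area_total_px2,
      area_left = df$area_left_px2, area_right = df$area_right_px2,
      length = if ("length_px" %in% names(df)) df$length_px else NA_real_
    ),
    fs = 1 / stats::median(diff(df$t_s))
  )
}

#' Read and write pressure traces as CSV
#'
#' Dialect: columns `t_s`, `p_pa`.
#' @param pressure A pressure tibble (`t`, `p_pa`).
#' @param path File path.
#' @export
write_pressure_csv <- function(pressure, path) {
  readr::write_csv(tibble(t_s = pressure$t, p_pa = pressure$p_pa), path)
  invisible(path)
}

#' @rdname write_pressure_csv
#' @export
read_pressure_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(df, c("t_s", "p_pa"), "Pressure CSV")
  out <- tibble(t = df$t_s, p_pa = df$p_pa)
  attr(out, "fs") <- 1 / stats::median(diff(df$t_s))
  out
}

#' Write and read WAV audio
#'
#' Minimal RIFF/WAVE support for mono IEEE float32 (default, lossless for
#' this package's signals) and 16-bit PCM.
#'
#' @param audio An audio tibble (`t`, `amplitude`) or numeric vector.
#' @param path File path.
#' @param fs Sampling rate; inferred from `audio` when `NULL`.
#' @param format `"float32"` or `"pcm16"`. PCM samples are scaled by the
#'   signal's absolute maximum, recorded nowhere: round-trips of PCM data
#'   preserve shape within 1 least-significant bit of full scale.
#' @return `read_wav()` returns an audio tibble with an `fs` attribute.
#' @export
write_wav <- function(audio, path, fs = NULL, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  fs <- round(resolve_fs(audio, fs))
  x <- signal_values(audio, "amplitude")
  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "float32") {
    audio_fmt <- 3L; bits <- 32L
    payload <- writeBin(x, raw(), size = 4, endian = "little")
  } else {
    audio_fmt <- 1L; bits <- 16L
    peak <- max(abs(x), .Machine$double.eps)
    q <- as.integer(round(x / peak * 32767))
    payload <- writeBin(q, raw(), size = 2, endian = "little")
  }
  block <- bits %/% 8L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + length(payload)), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(audio_fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * block), con, size = 4, endian = "little")
  writeBin(as.integer(block), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(length(payload)), con, size = 4, endian = "little")
  writeBin(payload, con)
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (riff != "RIFF" || wave != "WAVE") {
    phono_abort("Not a RIFF/WAVE file.", class = "phonolab_error_format")
  }
  fs <- NULL; audio_fmt <- NULL; bits <- NULL; x <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      audio_fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (sz > 16L) readBin(con, "raw", sz - 16L)
    } else if (id == "data") {
      if (is.null(audio_fmt)) {
        phono_abort("Malformed WAV: data chunk before fmt chunk.",
                    class = "phonolab_error_format")
      }
      if (audio_fmt == 3L && bits == 32L) {
        x <- readBin(con, "numeric", sz %/% 4L, size = 4, endian = "little")
      } else if (audio_fmt == 1L && bits == 16L) {
        x <- readBin(con, "integer", sz %/% 2L, size = 2, endian = "little") / 32767
      } else {
        phono_abort(sprintf("Unsupported WAV encoding (format %d, %d bit).",
                            audio_fmt, bits),
                    class = "phonolab_error_format")
      }
      break
    } else {
      readBin(con, "raw", sz)
    }
  }
  if (is.null(x)) phono_abort("WAV file has no data chunk.", class = "phonolab_error_format")
  out <- tibble(t = (seq_along(x) - 1L) / fs, amplitude = x)
  attr(out, "fs") <- fs
  out
}

#' Read and write measurement tables
#'
#' One row per measurement: `flow_slm`, `stretch_mm`, then the fifteen
#' phonation parameters.
#' @param table A measurement tibble (see [phonation_table()]).
#' @param path File path.
#' @export
write_parameter_table <- function(table, path) {
  out <- dplyr::rename(as_tibble(table), flow_slm = "flow", stretch_mm = "stretch")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_parameter_table
#' @export
read_parameter_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(df, c("flow_slm", "stretch_mm"), "Parameter CSV")
  dplyr::rename(df, flow = "flow_slm", stretch = "stretch_mm")
}

#' Write a significance report to CSV and JSON
#'
#' `<stem>.csv` holds the wide table-shaped view; `<stem>.json` holds the
#' full long results plus the design metadata.
#'
#' @param report A `phonation_report`.
#' @param stem Output path without extension.
#' @export
write_report <- function(report, stem) {
  readr::write_csv(report_wide(report), paste0(stem, ".csv"))
  jsonlite::write_json(
    list(
      design = report$design,
      alpha_kw = report$alpha_kw,
      alpha_posthoc = report$alpha_posthoc,
      alpha_posthoc_display = report$alpha_posthoc_display,
      results = report$results
    ),
    paste0(stem, ".json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(stem)
}
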