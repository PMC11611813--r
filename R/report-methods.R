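# broom-style and display methods for phonation_report objects.

#' @export
print.phonation_report <- function(x, digits = 3, ...) {
  cat(sprintf("<phonation_report: %s design>\n", x$design))
  cat(sprintf("  Kruskal-Wallis screening at p < %.2f; post hoc Mann-Whitney at p < %s\n",
              x$alpha_kw, format(x$alpha_posthoc_display)))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s (n=%d)", names(x$group_sizes), x$group_sizes),
                    collapse = ", ")))
  w <- report_wide(x)
  print(as.data.frame(w), digits = digits, row.names = FALSE)
  invisible(x)
}

#' Tidy a significance report
#'
#' @param x A `phonation_report`.
#' @param ... Unused.
#' @return The long results tibble: one row per parameter and comparison
#'   (the `"KW"` row is the screening test), with `p_value`, `significant`,
#'   `skipped`, `method`.
#' @export
tidy.phonation_report <- function(x, ...) {
  x$results
}

#' One-row-per-parameter summary of a significance report
#'
#' @param x A `phonation_report`.
#' @param ... Unused.
#' @return A tibble with `parameter`, `kw_p`, `kw_significant`,
#'   `n_significant_pairs`, `n_skipped_pairs`.
#' @export
glance.phonation_report <- function(x, ...) {
  x$results |>
    dplyr::filter(.data$comparison != "KW") |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      kw_p = .data$kw_p[1],
      kw_significant = .data$kw_p[1] < x$alpha_kw,
      n_significant_pairs = sum(.data$significant),
      n_skipped_pairs = sum(.data$skipped),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$parameter, phonation_parameters()))
}

#' Wide (table-shaped) view of a significance report
#'
#' One row per parameter, one column per pairwise comparison; skipped cells
#' are printed as `"-"`, significant p-values are marked with `*`.
#'
#' @param x A `phonation_report`.
#' @param digits Digits for p-value formatting (default 3).
#' @return A tibble with character columns `parameter`, `KW`, then one per
#'   comparison.
#' @export
report_wide <- function(x, digits = 3) {
  fmt <- function(p, sig, skip) {
    dplyr::case_when(
      skip ~ "-",
      !is.finite(p) ~ "NA",
      sig ~ paste0(formatC(p, digits = digits, format = "g"), "*"),
      TRUE ~ formatC(p, digits = digits, format = "g")
    )
  }
  x$results |>
    dplyr::mutate(cell = fmt(.data$p_value, .data$significant, .data$skipped)) |>
    dplyr::select("parameter", "comparison", "cell") |>
    tidyr::pivot_wider(names_from = "comparison", values_from = "cell") |>
    dplyr::arrange(match(.data$parameter, phonation_parameters()))
}

#' @export
autoplot.phonation_report <- function(object, ...) {
  d <- object$results |>
    dplyr::mutate(
      parameter = factor(.data$parameter, levels = rev(phonation_parameters())),
      comparison = factor(.data$comparison,
                          levels = c("KW", object$comparisons$label)),
      neglog_p = -log10(pmax(.data$p_value, 1e-6))
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$comparison, y = .data$parameter)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$neglog_p), color = "grey80") +
    ggplot2::geom_point(
      data = dplyr::filter(d, .data$significant),
      shape = 8, size = 1.5
    ) +
    ggplot2::geom_text(
      data = dplyr::filter(d, .data$skipped),
      label = "-", size = 3
    ) +
    ggplot2::scale_fill_viridis_c(na.value = "white", name = "-log10 p") +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("Nonparametric group tests (%s design)", object$design),
      subtitle = sprintf("* p < %s after Bonferroni; '-' post hoc skipped (KW p >= %.2f)",
                         format(object$alpha_posthoc_display), object$alpha_kw)
    ) +
    ggplot2::theme_minimal()
}
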