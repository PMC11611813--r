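# ggplot2 convenience views of waveforms and grouped parameters.

#' @export
autoplot.gaw_df <- function(object, ...) {
  d <- tidyr::pivot_longer(
    as_tibble(object)[c("t", "area_total", "area_left", "area_right")],
    -"t", names_to = "series", values_to = "area"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$area,
                                  color = .data$series)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "time (s)", y = expression("glottal area (px"^2 * ")"),
                  color = NULL, title = "Glottal area waveform") +
    ggplot2::theme_minimal()
}

#' Boxplots of one parameter across a design's groups
#'
#' Mirrors the experiment's boxplot conventions: median line, mean cross,
#' outlier circles, whiskers at 1.5 IQR.
#'
#' @param table A measurement tibble (see [phonation_table()]).
#' @param parameter Parameter column name (e.g. `"Psub"`).
#' @param design `"flow"` or `"stretch"`.
#' @return A ggplot object.
#' @export
plot_parameter_boxes <- function(table, parameter, design = c("flow", "stretch")) {
  design <- match.arg(design)
  d <- as_tibble(table)
  if (design == "flow") {
    d <- assign_flow_groups(d)
    d$group <- d$flow_group
  } else {
    d$group <- factor(d$stretch, labels = paste0(sort(unique(d$stretch)), " mm"))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data[[parameter]])) +
    ggplot2::geom_boxplot(outlier.shape = 1, coef = 1.5) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 4, size = 2.5) +
    ggplot2::labs(
      x = if (design == "flow") "flow rate group" else "stretching length",
      y = parameter
    ) +
    ggplot2::theme_minimal()
}
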