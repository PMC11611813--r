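# Grouped nonparametric testing: flow-group assignment, stretch pairs,
# Kruskal-Wallis screening, Mann-Whitney post hoc under Bonferroni
# correction, and boxplot-style summaries.

#' The canonical phonation parameter set
#'
#' Column names of the fifteen parameters a full measurement record
#' carries: the two general phonation parameters (F0, Psub), nine waveform
#' parameters and four acoustic parameters.
#' @return A character vector of length 15.
#' @export
phonation_parameters <- function() {
  c("F0", "Psub", "AP", "TP", "ASI", "PAI", "GGI", "ClQ", "MADR",
    "stiff", "ALR", "CPP", "HNR", "jitt", "shim")
}

#' Assign flow-rate groups
#'
#' Labels each row FG1-FG4 by exact membership of its flow value in the
#' canonical group value sets (FG1: 30-40 SLM in steps of 2; FG2: 50-80;
#' FG3: 90-120; FG4: 130-200 in steps of 10). Flows outside the sets are
#' assigned to the nearest group by its boundary, with a warning.
#'
#' @param table A data frame with a `flow` column (SLM).
#' @return The input with a `flow_group` factor column (levels FG1-FG4).
#' @examples
#' assign_flow_groups(tibble::tibble(flow = c(30, 60, 200)))
#' @export
assign_flow_groups <- function(table) {
  if (!is.data.frame(table) || !"flow" %in% names(table)) {
    phono_abort("`table` must contain a `flow` column.", class = "phonolab_error_format")
  }
  label_one <- function(f) {
    hit <- names(flow_group_values)[vapply(flow_group_values, function(v) f %in% v, logical(1))]
    if (length(hit) == 1L) return(hit)
    rlang::warn(sprintf("Flow %g SLM is not a listed group value; assigning by nearest boundary.", f),
                class = "phonolab_warning_flow_group")
    if (f < 45) "FG1" else if (f < 85) "FG2" else if (f < 125) "FG3" else "FG4"
  }
  labels <- vapply(table$flow, label_one, character(1))
  dplyr::mutate(
    as_tibble(table),
    flow_group = factor(labels, levels = names(flow_group_values))
  )
}

#' Ordered pairwise comparisons of stretching lengths
#'
#' All unordered pairs of the supplied stretch levels, ordered by the first
#' then the second member (for the canonical five levels 0, 5, 10, 15,
#' 20 mm this reproduces the S1-S10 comparison order: 0-5, 0-10, ...,
#' 15-20).
#'
#' @param levels Numeric stretch levels (mm); at least two.
#' @return A tibble with columns `pair` (S1, S2, ...), `a`, `b` and
#'   `label` (e.g. `"0mm-5mm"`).
#' @export
stretch_pairs <- function(levels) {
  levels <- sort(unique(as.numeric(levels)))
  if (length(levels) < 2L) {
    phono_abort("At least two stretch levels are required for pairwise tests.",
                class = "phonolab_error_design")
  }
  cmb <- utils::combn(levels, 2)
  tibble(
    pair = paste0("S", seq_len(ncol(cmb))),
    a = cmb[1, ], b = cmb[2, ],
    label = sprintf("%gmm-%gmm", cmb[1, ], cmb[2, ])
  )
}

#' Kruskal-Wallis rank test across groups
#'
#' Thin tidy wrapper around [stats::kruskal.test()] (tie-corrected H,
#' chi-square approximation with groups - 1 degrees of freedom). Groups in
#' which every pooled value is identical are degenerate: the test is
#' reported with `statistic = 0` and `p_value = 1`.
#'
#' @param data A data frame.
#' @param value,group Column names (strings) of the response and the
#'   grouping variable.
#' @return A one-row tibble: `statistic` (H), `df`, `p_value`, `n`.
#' @examples
#' d <- tibble::tibble(y = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
#'                     g = rep(c("a", "b", "c"), each = 3))
#' kruskal_wallis(d, "y", "g")  # H = 7.2
#' @export
kruskal_wallis <- function(data, value, group) {
  y <- data[[value]]
  g <- factor(data[[group]])
  keep <- stats::complete.cases(y, g)
  y <- y[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2L || any(tabulate(g) == 0L)) {
    phono_abort("Kruskal-Wallis needs at least two non-empty groups.",
                class = "phonolab_error_design")
  }
  if (length(unique(y)) == 1L) {
    return(tibble(statistic = 0, df = nlevels(g) - 1L, p_value = 1, n = length(y)))
  }
  kt <- stats::kruskal.test(y, g)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value, n = length(y))
}

# Two-sided Mann-Whitney U: exact-enumeration p when the combined sample is
# small and tie-free, tie-corrected normal approximation (with continuity
# correction) otherwise.
mann_whitney <- function(x, y, exact_max_n = 16L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0L || length(y) == 0L) {
    return(tibble(statistic = NA_real_, p_value = NA_real_, method = "skipped:empty"))
  }
  if (length(unique(c(x, y))) == 1L) {
    return(tibble(statistic = length(x) * length(y) / 2, p_value = 1,
                  method = "degenerate"))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y)) <= exact_max_n
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         method = if (exact) "exact" else "normal_approx")
}

#' Five-number boxplot summary per group
#'
#' Median, mean, linear-interpolation quartiles, whiskers at the most
#' extreme observations within 1.5 IQR of the box, and outliers beyond the
#' whiskers — the summary convention used for the experiment's boxplots
#' (median line, mean cross, outlier circles).
#'
#' @param data A data frame.
#' @param value,group Column names (strings) of the response and grouping
#'   variable.
#' @return A tibble with one row per group: `group`, `n`, `median`, `mean`,
#'   `q1`, `q3`, `whisker_low`, `whisker_high`, and a list-column
#'   `outliers`.
#' @export
boxplot_summary <- function(data, value, group = NULL) {
  df <- as_tibble(data)
  if (is.null(group)) {
    df$.group <- "all"
    group <- ".group"
  }
  df |>
    dplyr::group_by(group = .data[[group]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data[[value]]),
      mean = mean(.data[[value]]),
      q1 = stats::quantile(.data[[value]], 0.25, type = 7, names = FALSE),
      q3 = stats::quantile(.data[[value]], 0.75, type = 7, names = FALSE),
      whisker_low = {
        fence <- .data$q1 - 1.5 * (.data$q3 - .data$q1)
        min(.data[[value]][.data[[value]] >= fence])
      },
      whisker_high = {
        fence <- .data$q3 + 1.5 * (.data$q3 - .data$q1)
        max(.data[[value]][.data[[value]] <= fence])
      },
      outliers = list({
        iqr <- .data$q3 - .data$q1
        v <- .data[[value]]
        v[v < .data$q1 - 1.5 * iqr | v > .data$q3 + 1.5 * iqr]
      }),
      .groups = "drop"
    )
}

#' Grouped significance report (Kruskal-Wallis + Mann-Whitney post hoc)
#'
#' For every phonation parameter present in the table: a Kruskal-Wallis
#' test across the design's groups at alpha = 0.05, followed — only when
#' the screening test is significant — by two-sided pairwise Mann-Whitney
#' U tests under the Bonferroni-corrected level `0.05 / n_pairs` (0.0083
#' for the four flow groups, 0.005 for the ten stretch pairs). Pairs of a
#' parameter whose Kruskal-Wallis p is not below 0.05 are reported as
#' skipped, mirroring the "-" convention of the summary tables.
#'
#' @param table A measurement table with `flow` and/or `stretch` columns
#'   plus parameter columns (see [phonation_table()]).
#' @param design `"flow"` (groups FG1-FG4) or `"stretch"` (the stretch
#'   levels, compared pairwise).
#' @param parameters Parameter columns to test; defaults to the
#'   intersection of [phonation_parameters()] with the table.
#' @param alpha_kw Screening level (default 0.05).
#' @return An object of class `phonation_report`: a list with `results`
#'   (long tibble: `parameter`, `kw_p`, `comparison`, `p_value`,
#'   `significant`, `skipped`, `method`), `design`, `alpha_kw`,
#'   `alpha_posthoc`, `alpha_posthoc_display`, `comparisons`,
#'   `group_sizes`. Use [tidy()], [glance()], [report_wide()] or
#'   [autoplot()] on it.
#' @examples
#' \donttest{
#' sim <- simulate_experiment(seed = 1)
#' tab <- phonation_table(sim)
#' rep <- significance_report(tab, design = "flow")
#' glance(rep)
#' }
#' @export
significance_report <- function(table, design = c("flow", "stretch"),
                                parameters = NULL, alpha_kw = 0.05) {
  design <- match.arg(design)
  table <- as_tibble(table)
  if (is.null(parameters)) {
    parameters <- intersect(phonation_parameters(), names(table))
  }
  missing_par <- setdiff(phonation_parameters(), names(table))

  if (design == "flow") {
    table <- assign_flow_groups(table)
    glev <- names(which(table(table$flow_group) > 0))
    cmb <- utils::combn(glev, 2)
    comparisons <- tibble(
      pair = paste0(cmb[1, ], "-", cmb[2, ]),
      a = cmb[1, ], b = cmb[2, ],
      label = paste0(cmb[1, ], "-", cmb[2, ])
    )
    group_of <- as.character(table$flow_group)
  } else {
    comparisons <- stretch_pairs(unique(table$stretch))
    comparisons$a <- as.character(comparisons$a)
    comparisons$b <- as.character(comparisons$b)
    group_of <- as.character(table$stretch)
  }
  n_pairs <- nrow(comparisons)
  alpha_posthoc <- 0.05 / n_pairs

  if (length(unique(group_of)) < 2L) {
    phono_abort("The design needs at least two populated groups.",
                class = "phonolab_error_design")
  }

  res <- lapply(parameters, function(p) {
    y <- table[[p]]
    kw <- kruskal_wallis(tibble(y = y, g = group_of), "y", "g")
    gate_open <- is.finite(kw$p_value) && kw$p_value < alpha_kw
    pw <- lapply(seq_len(n_pairs), function(k) {
      a <- comparisons$a[k]; b <- comparisons$b[k]
      if (!gate_open) {
        return(tibble(comparison = comparisons$label[k], p_value = NA_real_,
                      significant = FALSE, skipped = TRUE, method = "skipped"))
      }
      mw <- mann_whitney(y[group_of == a], y[group_of == b])
      skipped <- startsWith(mw$method, "skipped")
      tibble(comparison = comparisons$label[k], p_value = mw$p_value,
             significant = !skipped && is.finite(mw$p_value) && mw$p_value < alpha_posthoc,
             skipped = skipped, method = mw$method)
    })
    dplyr::bind_rows(
      tibble(comparison = "KW", p_value = kw$p_value,
             significant = gate_open, skipped = FALSE, method = "kruskal_wallis"),
      dplyr::bind_rows(pw)
    ) |>
      dplyr::mutate(parameter = p, kw_p = kw$p_value, .before = 1)
  })

  structure(
    list(
      results = dplyr::bind_rows(res),
      design = design,
      alpha_kw = alpha_kw,
      alpha_posthoc = alpha_posthoc,
      alpha_posthoc_display = round(alpha_posthoc, 4),
      comparisons = comparisons,
      group_sizes = table(group_of),
      missing_parameters = missing_par
    ),
    class = "phonation_report"
  )
}

#' Family-wise false-positive rate of the gated post hoc procedure
#'
#' Monte-Carlo null simulation: draws groups with no group effect
#' (iid standard normal), runs the Kruskal-Wallis gate plus Bonferroni
#' post hoc, and returns the fraction of replicates in which any pairwise
#' comparison is flagged significant.
#'
#' @param n_reps Number of null replicates.
#' @param group_sizes Integer vector of group sizes.
#' @param seed Integer seed.
#' @param alpha_kw Screening level (default 0.05).
#' @return A one-row tibble with `fwer`, `n_reps`, `alpha_posthoc`.
#' @export
simulate_null_fwer <- function(n_reps = 1000L, group_sizes = c(18L, 18L, 20L, 20L),
                               seed = 1L, alpha_kw = 0.05) {
  n_groups <- length(group_sizes)
  cmb <- utils::combn(n_groups, 2)
  alpha_posthoc <- 0.05 / ncol(cmb)
  g <- rep(seq_len(n_groups), group_sizes)
  hits <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      y <- stats::rnorm(sum(group_sizes))
      kw <- stats::kruskal.test(y, factor(g))
      if (!is.finite(kw$p.value) || kw$p.value >= alpha_kw) return(FALSE)
      for (k in seq_len(ncol(cmb))) {
        p <- mann_whitney(y[g == cmb[1, k]], y[g == cmb[2, k]])$p_value
        if (is.finite(p) && p < alpha_posthoc) return(TRUE)
      }
      FALSE
    }, logical(1))
  })
  tibble(fwer = mean(hits), n_reps = n_reps, alpha_posthoc = alpha_posthoc)
}
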