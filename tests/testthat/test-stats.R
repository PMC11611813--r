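# Grouped nonparametric testing: groups, pairs, tests, summaries, reports.

test_that("flow groups follow the canonical value sets", {
  tab <- assign_flow_groups(tibble::tibble(flow = c(30, 40, 50, 80, 90, 120, 130, 200)))
  expect_equal(as.character(tab$flow_group),
               c("FG1", "FG1", "FG2", "FG2", "FG3", "FG3", "FG4", "FG4"))
  expect_warning(assign_flow_groups(tibble::tibble(flow = 44)),
                 class = "phonolab_warning_flow_group")
  tab2 <- suppressWarnings(assign_flow_groups(tibble::tibble(flow = c(44, 46, 210))))
  expect_equal(as.character(tab2$flow_group), c("FG1", "FG2", "FG4"))
})

test_that("stretch pairs enumerate in the canonical order", {
  p <- stretch_pairs(c(0, 5, 10, 15, 20))
  expect_equal(nrow(p), 10)
  expect_equal(p$pair, paste0("S", 1:10))
  expect_equal(c(p$a[1], p$b[1]), c(0, 5))
  expect_equal(c(p$a[10], p$b[10]), c(15, 20))
  expect_equal(p$label[2], "0mm-10mm")
  expect_equal(nrow(stretch_pairs(c(0, 5))), 1)
  expect_equal(nrow(stretch_pairs(c(0, 5, 10))), choose(3, 2))
  expect_error(stretch_pairs(5), class = "phonolab_error_design")
})

test_that("Kruskal-Wallis matches the longhand rank formula", {
  groups <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  d <- tibble::tibble(y = unlist(groups),
                      g = rep(c("a", "b", "c"), each = 3))
  kw <- kruskal_wallis(d, "y", "g")
  expect_equal(kw$statistic, 7.2, tolerance = 1e-9)
  expect_equal(kw$statistic, oracle_kw_H(groups), tolerance = 1e-12)
  expect_equal(kw$p_value, pchisq(7.2, df = 2, lower.tail = FALSE), tolerance = 1e-9)
  # two statistically identical groups: H near 0, p near 1
  d2 <- tibble::tibble(y = rep(c(1, 2, 3, 4), 2), g = rep(c("a", "b"), each = 4))
  kw2 <- kruskal_wallis(d2, "y", "g")
  expect_lt(kw2$statistic, 0.1)
  expect_gt(kw2$p_value, 0.9)
})

test_that("Kruskal-Wallis H is chi-square distributed under the null", {
  H <- withr::with_seed(99, vapply(1:400, function(i) {
    d <- tibble::tibble(y = rnorm(45), g = rep(c("a", "b", "c"), each = 15))
    kruskal_wallis(d, "y", "g")$statistic
  }, numeric(1)))
  ks <- suppressWarnings(stats::ks.test(H, function(q) pchisq(q, df = 2)))
  expect_gt(ks$p.value, 0.001)
})

test_that("exact Mann-Whitney equals full enumeration", {
  expect_equal(phonolab:::mann_whitney(c(1, 2), c(3, 4))$p_value, 1 / 3,
               tolerance = 1e-12)
  withr::with_seed(7, {
    for (m in 2:5) {
      for (n in 2:5) {
        x <- rnorm(m); y <- rnorm(n, mean = 0.5)
        mw <- phonolab:::mann_whitney(x, y)
        expect_equal(mw$method, "exact")
        expect_equal(mw$p_value, oracle_mw_exact_p(x, y), tolerance = 1e-12,
                     label = sprintf("m=%d n=%d", m, n))
      }
    }
  })
})

test_that("Mann-Whitney degenerate and large-sample paths behave", {
  expect_equal(phonolab:::mann_whitney(rep(1, 5), rep(1, 6))$p_value, 1)
  big <- phonolab:::mann_whitney(rnorm(20), rnorm(20))
  expect_equal(big$method, "normal_approx")
  expect_true(big$p_value >= 0 && big$p_value <= 1)
  expect_equal(phonolab:::mann_whitney(numeric(0), 1:3)$method, "skipped:empty")
})

test_that("boxplot summaries follow the 1.5 IQR convention", {
  d <- tibble::tibble(v = c(1, 2, 3, 4, 100))
  s <- boxplot_summary(d, "v")
  expect_equal(s$median, 3)
  expect_equal(s$mean, 22)
  expect_equal(s$q1, 2); expect_equal(s$q3, 4)
  expect_equal(s$outliers[[1]], 100)
  expect_equal(s$whisker_high, 4)
  # single value: median = mean = value, no outliers
  s1 <- boxplot_summary(tibble::tibble(v = 7), "v")
  expect_equal(s1$median, 7); expect_equal(s1$mean, 7)
  expect_length(s1$outliers[[1]], 0)
  # symmetric data: mean equals median
  s2 <- boxplot_summary(tibble::tibble(v = c(1, 2, 3, 4, 5)), "v")
  expect_equal(s2$mean, s2$median)
})

test_that("report thresholds and gating mirror the two designs", {
  withr::with_seed(3, {
    tab <- tibble::tibble(
      flow = rep(c(30, 60, 100, 150), each = 8),
      stretch = rep(c(0, 5, 10, 15, 20), length.out = 32),
      F0 = rnorm(32, 250, 5) + rep(c(30, 60, 100, 150), each = 8) / 10,
      Psub = rnorm(32, 1500, 50)
    )
  })
  rf <- significance_report(tab, design = "flow")
  expect_equal(rf$alpha_posthoc_display, 0.0083)
  expect_equal(rf$alpha_posthoc, 0.05 / 6, tolerance = 1e-12)
  rs <- significance_report(tab, design = "stretch")
  expect_equal(rs$alpha_posthoc_display, 0.005)
  expect_equal(rs$alpha_posthoc, 0.05 / 10, tolerance = 1e-12)

  # skipped cells appear exactly when the screening test is not significant
  long <- tidy(rf) |> dplyr::filter(comparison != "KW")
  gate <- tidy(rf) |> dplyr::filter(comparison == "KW")
  for (p in unique(long$parameter)) {
    kw_sig <- gate$p_value[gate$parameter == p] < 0.05
    cells <- long[long$parameter == p, ]
    if (kw_sig) expect_true(all(!cells$skipped))
    else expect_true(all(cells$skipped))
    ok <- cells$skipped | (cells$p_value >= 0 & cells$p_value <= 1)
    expect_true(all(ok))
  }
  # wide view prints "-" for skipped cells
  w <- report_wide(rf)
  if (any(long$skipped)) expect_true(any(w[-1] == "-"))
  g <- glance(rf)
  expect_true(all(c("parameter", "kw_p", "n_significant_pairs") %in% names(g)))
})

test_that("null simulation keeps the family-wise error at the Bonferroni bound", {
  r <- simulate_null_fwer(n_reps = 300, group_sizes = c(18, 18, 20, 20), seed = 2)
  expect_lte(r$fwer, 0.05 + 2 * sqrt(0.05 * 0.95 / 300))
})
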