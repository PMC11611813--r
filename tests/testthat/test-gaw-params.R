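# Waveform parameters: periodicity, symmetry, closure, elasticity.

# Hand-built cycle tables let each index be checked against direct evaluation
# of its defining formula.
make_cycle_table <- function(n = 24, amp = rep(1, n), dur = rep(5e-3, n),
                             amp_l = amp, amp_r = amp,
                             lag_frac = rep(0, n)) {
  t0 <- cumsum(c(0, dur))[seq_len(n)]
  tibble::tibble(
    cycle = seq_len(n), t_start = t0, t_end = t0 + dur, duration = dur,
    a_min = 0, a_max = amp, a_range = amp, a_osc = amp,
    t_peak = t0 + dur / 2,
    a_range_left = amp_l, a_range_right = amp_r,
    a_osc_left = amp_l, a_osc_right = amp_r,
    t_peak_left = t0 + dur / 2,
    t_peak_right = t0 + dur / 2 + lag_frac * dur,
    s_max = amp * 100, closing_rate_max = amp * 50,
    t_min_after_peak = t0 + dur, closed_frac = 0
  )
}

test_that("identical cycles give perfect periodicity and symmetry", {
  cyc <- make_cycle_table()
  p <- periodicity_indices(cyc)
  expect_identical(c(p$AP, p$TP), c(1, 1))
  s <- symmetry_indices(cyc)
  expect_identical(c(s$ASI, s$PAI), c(1, 0))
})

test_that("periodicity matches direct evaluation of the pairwise-ratio mean", {
  cyc <- make_cycle_table(amp = rep(c(1, 0.8), 12))
  expect_equal(periodicity_indices(cyc)$AP, 0.8, tolerance = 1e-12)
  cyc <- make_cycle_table(dur = rep(c(5.0e-3, 5.2e-3), 12))
  expect_equal(periodicity_indices(cyc)$TP, 5.0 / 5.2, tolerance = 1e-12)
})

test_that("symmetry indices match their ratio and phase-lag definitions", {
  cyc <- make_cycle_table(amp_l = rep(0.5, 24), amp_r = rep(1, 24))
  expect_equal(symmetry_indices(cyc)$ASI, 0.5, tolerance = 1e-12)
  cyc <- make_cycle_table(lag_frac = rep(0.25, 24))
  expect_equal(symmetry_indices(cyc)$PAI, 0.25, tolerance = 1e-12)
})

test_that("degenerate cycle tables raise typed errors", {
  cyc <- make_cycle_table(amp = c(0, rep(1, 23)))
  err <- expect_error(periodicity_indices(cyc), class = "phonolab_error_degenerate")
  expect_match(conditionMessage(err), "1")
  cyc <- make_cycle_table(amp_l = rep(0, 24))
  expect_error(symmetry_indices(cyc), class = "phonolab_error_one_sided")
  expect_error(periodicity_indices(make_cycle_table(n = 5)),
               class = "phonolab_error_insufficient_cycles")
})

test_that("GGI matches the min/max ratio on a sinusoid", {
  # A between 50 and 150 px^2 -> GGI = 1/3
  gaw <- make_sine_gaw(a0 = 100, a = 50)
  ci <- closure_indices(detect_cycles(gaw))
  expect_equal(ci$GGI, 1 / 3, tolerance = 0.005)
  # complete closure -> GGI = 0
  gaw0 <- generate_gaw(base_spec(baseline_gap = 0))
  ci0 <- closure_indices(detect_cycles(gaw0))
  expect_equal(ci0$GGI, 0, tolerance = 1e-6)
})

test_that("ClQ and MADR follow closed forms on a sinusoid", {
  gaw <- make_sine_gaw(f = 200, a0 = 2e5, a = 1e5)  # a = 0.1 Mpx
  ci <- closure_indices(detect_cycles(gaw))
  expect_equal(ci$ClQ, 0.5, tolerance = 0.005)
  expect_equal(ci$MADR, 2 * pi * 200 * 0.1, tolerance = 0.005)
  # closed-phase reading on a non-closing sinusoid is zero
  ci2 <- closure_indices(detect_cycles(gaw), clq_method = "closed_phase")
  expect_equal(ci2$ClQ, 0, tolerance = 1e-9)
})

test_that("stiffness matches the per-cycle derivative-ratio closed form", {
  gaw <- make_sine_gaw(f = 200, length_px = 100)
  cyc <- detect_cycles(gaw)
  ei <- elasticity_indices(cyc)
  expect_equal(ei$stiff, pi * 200, tolerance = 0.005)
  # doubling f doubles stiff
  ei2 <- elasticity_indices(detect_cycles(make_sine_gaw(f = 400, length_px = 100)))
  expect_equal(ei2$stiff / ei$stiff, 2, tolerance = 0.01)
})

test_that("pipeline stiffness agrees with a brute-force Eq-style oracle", {
  gaw <- make_sine_gaw(f = 200, length_px = 100)
  cyc <- detect_cycles(gaw)
  stiff_pkg <- elasticity_indices(cyc)$stiff
  xs <- as.numeric(signal::sgolayfilt(gaw$area_total, p = 3, n = 5))
  stiff_oracle <- oracle_stiff(gaw$t, xs, c(cyc$t_start, cyc$t_end[nrow(cyc)]))
  expect_equal(stiff_pkg, stiff_oracle, tolerance = 1e-4)
})

test_that("ALR follows its amplitude-to-length definition", {
  cyc <- make_cycle_table(amp = rep(200, 24))
  cyc$length_mean <- rep(100, 24)
  expect_equal(elasticity_indices(cyc)$ALR, 200 / (2 * 100^2), tolerance = 1e-12)
  cyc$length_mean <- NULL
  expect_equal(elasticity_indices(cyc, length_px = 100)$ALR, 0.01, tolerance = 1e-12)
  err <- tryCatch(elasticity_indices(cyc), error = identity)
  expect_s3_class(err, "phonolab_error_alr_unavailable")
  expect_true(is.finite(err$stiff))   # stiff still delivered with the error
})

test_that("all indices respect their ranges on random oscillator specs", {
  for (s in 1:8) {
    spec <- withr::with_seed(s, base_spec(
      f0 = runif(1, 150, 350),
      amp_left = runif(1, 10, 40), amp_right = runif(1, 10, 40),
      phase_offset_frac = runif(1, 0, 0.2),
      baseline_gap = runif(1, 0, 60),
      jitter_pct = runif(1, 0, 3), shimmer_pct = runif(1, 0, 3),
      seed = s
    ))
    p <- gaw_parameters(generate_gaw(spec))
    expect_true(p$AP >= 0 && p$AP <= 1)
    expect_true(p$TP >= 0 && p$TP <= 1)
    expect_true(p$ASI >= 0 && p$ASI <= 1)
    expect_true(p$PAI >= 0 && p$PAI <= 1)
    expect_true(p$GGI >= 0 && p$GGI <= 1)
    expect_true(p$ClQ >= 0 && p$ClQ <= 1)
    expect_true(p$MADR >= 0 && p$stiff >= 0 && p$ALR >= 0)
    expect_true(all(is.finite(unlist(p))))
  }
})

test_that("GGI grows with the baseline gap and PAI with the phase offset", {
  ggi <- vapply(c(30, 45, 60, 80), function(g) {
    closure_indices(detect_cycles(generate_gaw(base_spec(baseline_gap = g))))$GGI
  }, numeric(1))
  expect_true(all(diff(ggi) > 0))
  pai <- vapply(c(0, 0.05, 0.1, 0.2), function(ph) {
    symmetry_indices(detect_cycles(generate_gaw(
      base_spec(baseline_gap = 40, phase_offset_frac = ph)
    )))$PAI
  }, numeric(1))
  expect_true(all(diff(pai) > 0))
})

test_that("PAI recovers the generator phase offset", {
  s <- symmetry_indices(detect_cycles(generate_gaw(
    base_spec(baseline_gap = 40, phase_offset_frac = 0.25)
  )))
  expect_equal(s$PAI, 0.25, tolerance = 0.01)
})
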