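# Synthetic recording generators: waveform, audio, pressure.

test_that("symmetric specs give identical hemiglottal series", {
  gaw <- generate_gaw(base_spec(phase_offset_frac = 0, jitter_pct = 0,
                                shimmer_pct = 0))
  expect_identical(gaw$area_left, gaw$area_right)
  expect_equal(gaw$area_total, gaw$area_left + gaw$area_right)
})

test_that("zero baseline gap yields complete closure every cycle", {
  gaw <- generate_gaw(base_spec(baseline_gap = 0, jitter_pct = 0))
  cyc <- detect_cycles(gaw)
  expect_true(all(cyc$a_min <= 1e-9 * max(gaw$area_total)))
})

test_that("nominal cycle duration follows f0 and the frame rate", {
  gaw <- generate_gaw(base_spec(f0 = 200, fs_video = 4000))
  cyc <- detect_cycles(gaw)
  expect_equal(mean(cyc$duration), 5e-3, tolerance = 1e-3)
  expect_equal(mean(cyc$duration) * 4000, 20, tolerance = 1e-3)
})

test_that("generators are deterministic in the seed and vary across seeds", {
  s1 <- base_spec(jitter_pct = 1, shimmer_pct = 1, hnr_target = 20, seed = 7)
  s2 <- base_spec(jitter_pct = 1, shimmer_pct = 1, hnr_target = 20, seed = 8)
  expect_identical(generate_gaw(s1), generate_gaw(s1))
  expect_false(identical(generate_gaw(s1)$area_total, generate_gaw(s2)$area_total))
  expect_identical(generate_audio(s1), generate_audio(s1))
  expect_false(identical(generate_audio(s1)$amplitude, generate_audio(s2)$amplitude))
  expect_identical(generate_pressure(s1), generate_pressure(s1))
})

test_that("noise-free round trip recovers perfect periodicity", {
  # commensurate f0/fs so every cycle is sampled identically
  gaw <- generate_gaw(base_spec(f0 = 200, fs_video = 4000, jitter_pct = 0,
                                shimmer_pct = 0, baseline_gap = 30))
  p <- periodicity_indices(detect_cycles(gaw))
  expect_equal(p$AP, 1, tolerance = 1e-9)
  expect_equal(p$TP, 1, tolerance = 1e-9)
})

test_that("audio honours the HNR target exactly at generation", {
  clean <- generate_audio(base_spec(f0 = 220, n_cycles = 110, hnr_target = Inf))
  noisy <- generate_audio(base_spec(f0 = 220, n_cycles = 110, hnr_target = 0))
  noise <- noisy$amplitude - clean$amplitude
  expect_gt(max(abs(noise)), 0)
  expect_equal(mean(clean$amplitude^2) / mean(noise^2), 1, tolerance = 0.01)
  # Inf target: bit-identical harmonic part, no noise at all
  again <- generate_audio(base_spec(f0 = 220, n_cycles = 110, hnr_target = Inf))
  expect_identical(clean$amplitude, again$amplitude)
})

test_that("audio F0 round-trips through the autocorrelation estimator", {
  au <- generate_audio(base_spec(f0 = 220, n_cycles = 110, jitter_pct = 0))
  est <- phonolab:::estimate_f0_acf(au$amplitude, attr(au, "fs"))
  expect_equal(est$f0, 220, tolerance = 1 / 220)
})

test_that("audio generation refuses aliasing configurations", {
  expect_error(
    generate_audio(base_spec(f0 = 2000, fs_audio = 16000), n_harmonics = 8),
    class = "phonolab_error_aliasing"
  )
})

test_that("audio carries at least 100 cycles when requested", {
  au <- generate_audio(base_spec(f0 = 220, n_cycles = 110, jitter_pct = 0.8,
                                 shimmer_pct = 1, hnr_target = 25))
  p <- perturbation_indices(au)
  expect_gte(p$n_cycles_used, 100)
})

test_that("pressure trace has the exact requested mean and F0", {
  spec <- base_spec(f0 = 200, n_cycles = 200, psub_mean = 2000)
  pr <- generate_pressure(spec)
  expect_equal(mean(pr$p_pa), 2000, tolerance = 1e-12)
  pp <- pressure_parameters(pr)
  expect_equal(pp$Psub, 2000, tolerance = 10 / 2000)
  expect_equal(pp$F0, 200, tolerance = 1 / 200)
  # halving the ripple period doubles the estimated F0
  pr2 <- generate_pressure(base_spec(f0 = 400, n_cycles = 400, psub_mean = 2000))
  expect_equal(pressure_parameters(pr2)$F0, 400, tolerance = 1 / 400)
})

test_that("ripple- and noise-free pressure is a constant trace", {
  pr <- generate_pressure(base_spec(psub_mean = 1234), ripple_frac = 0,
                          noise_frac = 0)
  expect_true(all(abs(pr$p_pa - 1234) < 1e-9))
})
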