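# Acoustic measures: jitter/shimmer, CPP, HNR, and the pressure channel.

test_that("perfectly periodic audio has (numerically) zero jitter and shimmer", {
  au <- generate_audio(base_spec(f0 = 220, n_cycles = 110, hnr_target = Inf))
  p <- perturbation_indices(au)
  expect_lt(p$jitt, 1e-3)
  expect_lt(p$shim, 1e-3)
})

test_that("jitter matches direct evaluation on prescribed periods", {
  au <- make_pulse_train(periods = rep(c(5.0e-3, 5.2e-3), 60),
                         amps = rep(1, 120), fs = 44100)
  p <- perturbation_indices(au)
  expect_equal(p$jitt, 0.2 / 5.1 * 100, tolerance = 0.02)
  expect_lt(p$shim, 0.5)
})

test_that("shimmer matches direct evaluation on prescribed amplitudes", {
  au <- make_pulse_train(periods = rep(5e-3, 120),
                         amps = rep(c(1, 0.9), 60), fs = 44100)
  p <- perturbation_indices(au)
  expect_equal(p$shim, 0.1 / 0.95 * 100, tolerance = 0.15)
  expect_lt(p$jitt, 0.1)
})

test_that("too few cycles raise a counted error", {
  au <- generate_audio(base_spec(f0 = 220, n_cycles = 50, hnr_target = Inf))
  err <- tryCatch(perturbation_indices(au), error = identity)
  expect_s3_class(err, "phonolab_error_insufficient_cycles")
  expect_lt(err$n_detected, 100)
})

test_that("jitter and shimmer recover generator targets within 0.3 points", {
  errs <- vapply(1:20, function(s) {
    spec <- base_spec(f0 = 220, n_cycles = 110, jitter_pct = 1.5,
                      shimmer_pct = 2, hnr_target = Inf, seed = s)
    p <- perturbation_indices(generate_audio(spec, n_cycles = 105))
    c(p$jitt - 1.5, p$shim - 2)
  }, numeric(2))
  expect_lt(abs(mean(errs[1, ])), 0.3)
  expect_lt(abs(mean(errs[2, ])), 0.3)
})

test_that("HNR tracks the generator target within 1.5 dB over 5-30 dB", {
  for (target in c(5, 10, 20, 30)) {
    au <- generate_audio(base_spec(f0 = 220, n_cycles = 110,
                                   hnr_target = target, seed = 11))
    q <- quality_indices(au)
    expect_equal(q$HNR, target, tolerance = 1.5 / target, label = paste("HNR", target))
  }
})

test_that("HNR is monotone non-increasing in generator noise power", {
  hnr <- vapply(c(Inf, 30, 20, 10, 5, 0), function(h) {
    quality_indices(generate_audio(base_spec(f0 = 220, n_cycles = 110,
                                             hnr_target = h, seed = 5)))$HNR
  }, numeric(1))
  expect_true(all(diff(hnr) < 0))
  expect_lte(hnr[1], 40)   # cap on the noise-free signal
})

test_that("CPP drops when strong noise overlays a clean pulse train", {
  clean <- quality_indices(generate_audio(base_spec(f0 = 220, n_cycles = 110,
                                                    hnr_target = Inf, seed = 3)))
  noisy <- quality_indices(generate_audio(base_spec(f0 = 220, n_cycles = 110,
                                                    hnr_target = 3, seed = 3)))
  expect_gt(clean$CPP, noisy$CPP)
})

test_that("CPP agrees with an explicit-DFT oracle window by window", {
  au <- generate_audio(base_spec(f0 = 220, n_cycles = 115, hnr_target = 15, seed = 9))
  fs <- attr(au, "fs")
  x <- au$amplitude
  nw <- round(0.04 * fs)
  hop <- round(nw * 0.5)
  starts <- seq(1L, length(x) - nw + 1L, by = hop)
  oracle <- mean(vapply(starts, function(s) {
    oracle_cpp_window(x[s:(s + nw - 1L)], fs)
  }, numeric(1)))
  pkg <- quality_indices(au)$CPP
  expect_equal(pkg, oracle, tolerance = 0.1)
})

test_that("pure noise is reported unvoiced, with the mean still available", {
  noise <- withr::with_seed(1, tibble::tibble(
    t = (0:22049) / 44100, p_pa = 1500 + rnorm(22050, sd = 30)
  ))
  err <- tryCatch(pressure_parameters(noise), error = identity)
  expect_s3_class(err, "phonolab_error_unvoiced")
  expect_equal(err$psub, mean(noise$p_pa), tolerance = 1e-9)
})

test_that("short signals are refused", {
  au <- generate_audio(base_spec(f0 = 220, n_cycles = 30))
  expect_error(quality_indices(au), class = "phonolab_error_format")
  pr <- generate_pressure(base_spec(n_cycles = 20))
  expect_error(pressure_parameters(pr), class = "phonolab_error_format")
})
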