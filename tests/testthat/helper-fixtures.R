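# Shared fixtures built in code at test time.

# Analytic sinusoidal GAW: A(t) = a0 + a * sin(2 pi f t), in px^2.
make_sine_gaw <- function(f = 200, fs = 4000, n_cycles = 40, a0 = 2e5, a = 1e5,
                          length_px = NULL) {
  t <- seq(0, n_cycles / f, by = 1 / fs)
  t <- t[-length(t)]
  out <- tibble::tibble(t = t, area_total = a0 + a * sin(2 * pi * f * t))
  if (!is.null(length_px)) out$length <- rep(length_px, length(t))
  attr(out, "fs") <- fs
  out
}

# A small but fully featured oscillator used across tests.
base_spec <- function(...) {
  args <- utils::modifyList(
    list(f0 = 200, n_cycles = 40, amp_left = 25, amp_right = 25,
         baseline_gap = 0, glottal_length = 200, seed = 1L),
    list(...)
  )
  do.call(oscillator_spec, args)
}
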