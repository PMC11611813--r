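# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive each quantity from its definition with
# different code paths (explicit loops, direct DFT, enumeration).

# Brute-force stiffness: dense numerical differentiation of an interpolant
# of the waveform, explicit per-cycle max and ratio, arithmetic mean.
oracle_stiff <- function(t, A, boundaries_t, h = 1e-6) {
  f <- stats::splinefun(t, A, method = "fmm")
  vals <- numeric(length(boundaries_t) - 1L)
  for (i in seq_along(vals)) {
    tt <- seq(boundaries_t[i], boundaries_t[i + 1L], length.out = 4000L)
    s <- abs((f(tt + h) - f(tt - h)) / (2 * h))
    a_hat <- max(f(tt)) - min(f(tt))
    vals[i] <- max(s) / a_hat
  }
  mean(vals)
}

# Exact two-sided Mann-Whitney p by full enumeration of which pooled
# positions belong to the first sample.
oracle_mw_exact_p <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(m + n, m)
  u_all <- colSums(matrix(r[idx], nrow = m)) - m * (m + 1) / 2
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# Kruskal-Wallis H from the rank formula written out longhand (no ties
# assumed by the caller).
oracle_kw_H <- function(groups) {
  pooled <- unlist(groups)
  N <- length(pooled)
  r <- rank(pooled)
  offset <- 0L
  H <- 0
  for (g in groups) {
    idx <- offset + seq_along(g)
    H <- H + length(g) * (mean(r[idx]) - (N + 1) / 2)^2
    offset <- offset + length(g)
  }
  12 / (N * (N + 1)) * H
}

# Window-level cepstral peak prominence straight from the definition, using
# an explicit DFT matrix (no shared code with the package implementation).
oracle_cpp_window <- function(seg, fs, fmin = 60, fmax = 880) {
  nw <- length(seg)
  seg <- seg - mean(seg)
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))
  xw <- seg * hann
  nfft <- 2^ceiling(log2(2 * nw))
  xpad <- c(xw, numeric(nfft - nw))
  k <- 0:(nfft - 1)
  # explicit DFT of the padded window
  W <- exp(-2i * pi * outer(k, k) / nfft)
  X <- as.vector(W %*% xpad)
  log_spec <- 10 * log10(Mod(X)^2 + 1e-300)
  C <- as.vector(W %*% log_spec)
  cep <- 10 * log10(Mod(C)^2 + 1e-300)
  q_lo <- ceiling(fs / fmax); q_hi <- floor(fs / fmin)
  q <- (q_lo:q_hi) / fs
  band <- cep[(q_lo + 1L):(q_hi + 1L)]
  fit <- stats::lm(band ~ q)
  resid <- band - stats::fitted(fit)
  j <- which.max(resid)
  resid[j]
}

# Pulse train with fully prescribed per-cycle periods and peak amplitudes:
# one narrow Gaussian pulse per cycle at a fixed offset from the cycle
# onset, so pulse-to-pulse intervals equal the prescribed periods exactly.
# Periods land on arbitrary (non-integer) sample positions.
make_pulse_train <- function(periods, amps, fs) {
  onsets <- c(0, cumsum(periods))
  centers <- onsets[-length(onsets)] + min(periods) / 2
  n <- ceiling(onsets[length(onsets)] * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  sigma <- min(periods) / 12
  for (i in seq_along(centers)) {
    x <- x + amps[i] * exp(-(t - centers[i])^2 / (2 * sigma^2))
  }
  out <- tibble::tibble(t = t, amplitude = x)
  attr(out, "fs") <- fs
  out
}
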