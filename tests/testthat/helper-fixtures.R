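# Small construction helpers shared across test files. All fixtures are
# built in code; nothing is read from disk except the shipped ROI map.

# two-channel config with a single planted coupling and no confounds
coupled_config <- function(strength, seed, duration = 600, noise_sd = 0,
                           phase_lag = 0, band = c(0.02, 0.08),
                           oscillators = list(), drift = 0) {
  cohort_config(
    n_subjects = 2, duration = duration, channels = c("CH01", "CH02"),
    oscillators = oscillators,
    couplings = list(prior = list(
      coupling_spec(c("CH01", "CH02"), strength, phase_lag = phase_lag, band = band)
    )),
    drift_amplitude = drift, noise_sd = noise_sd,
    subject_kappa = list(mean = 1, sd = 0), # planted strength used as-is
    seed = seed
  )
}

# n-channel pure white-noise recording (independent channels)
noise_recording <- function(n_channels, duration, seed, fs = 13.33) {
  cfg <- cohort_config(
    n_subjects = 2, fs = fs, duration = duration,
    channels = sprintf("CH%02d", seq_len(n_channels)),
    oscillators = list(), couplings = list(prior = list()),
    drift_amplitude = 0, noise_sd = 1, seed = seed
  )
  generate_recording(cfg, 1, "prior")
}

# build a wavelet_decomposition around given complex coefficients
fake_decomposition <- function(coefs, freqs = seq_len(nrow(coefs)), fs = 10) {
  structure(
    list(
      coefficients = coefs, freqs = freqs, fs = fs,
      spec = wavelet_spec(freqs = freqs)
    ),
    class = "wavelet_decomposition"
  )
}

# independent textbook-formula oracles (loop style, no vectorized shortcuts)
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- 0
  sxx <- 0
  syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  r <- sxy / sqrt(sxx * syy)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

oracle_wpco <- function(dphi) {
  cs <- 0
  sn <- 0
  for (v in dphi) {
    cs <- cs + cos(v)
    sn <- sn + sin(v)
  }
  sqrt((cs / length(dphi))^2 + (sn / length(dphi))^2)
}
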