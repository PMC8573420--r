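fs <- 13.33

test_that("the six physiological intervals partition 0.0005-2 Hz contiguously", {
  b <- fnirs_bands()
  expect_equal(nrow(b), 6)
  # contiguous, non-overlapping, descending in frequency
  expect_equal(b$lo[-6], b$hi[-1])
  expect_true(all(b$hi > b$lo))
  ab <- analysis_band()
  expect_true(ab[1] >= 0.0005 && ab[2] <= 2)
  expect_equal(band_interval("neurogenic"), c(0.021, 0.052))
  expect_equal(band_interval("IV"), c(0.021, 0.052))
  expect_error(band_interval("gamma"), "unknown")
})

test_that("the transform is linear and maps zero to zero", {
  set.seed(3)
  n <- 3000
  spec <- wavelet_spec(freqs = wavelet_grid(0.02, 0.5, 6))
  z <- cwt_morlet(rep(0, n), fs, spec)
  expect_true(all(Mod(z$coefficients) == 0))
  x <- rnorm(n)
  expect_equal(
    cwt_morlet(2.5 * x, fs, spec)$coefficients,
    2.5 * cwt_morlet(x, fs, spec)$coefficients,
    tolerance = 1e-12
  )
})

test_that("a pure sinusoid's modulus peaks at its grid frequency", {
  n <- round(600 * fs)
  spec <- wavelet_spec(freqs = wavelet_grid(0.01, 0.1, 8))
  for (k in c(5, 14, 22)) {
    f0 <- spec$freqs[k]
    d <- cwt_morlet(sin(2 * pi * f0 * (0:(n - 1)) / fs), fs, spec)
    expect_equal(unname(which.max(wavelet_amplitude(d))), k)
  }
})

test_that("sinusoid phase advances at the analytic rate 2*pi*f0/fs", {
  n <- round(600 * fs)
  spec <- wavelet_spec(freqs = wavelet_grid(0.01, 0.1, 8))
  f0 <- spec$freqs[14]
  d <- cwt_morlet(cos(2 * pi * f0 * (0:(n - 1)) / fs), fs, spec, pad = "none")
  ph <- wavelet_phase(d)[14, ]
  steps <- diff(ph[1000:2000])
  steps <- (steps + pi) %% (2 * pi) - pi
  expect_equal(mean(steps), 2 * pi * f0 / fs, tolerance = 1e-4)
})

test_that("preconditions are enforced", {
  spec <- wavelet_spec(freqs = c(0.05, 8))
  expect_error(cwt_morlet(rnorm(1000), fs, spec), "Nyquist")
  spec2 <- wavelet_spec(freqs = c(0.01, 0.05))
  expect_error(cwt_morlet(rnorm(100), fs, spec2), "two cycles")
  expect_error(wavelet_spec(freqs = c(0.1, 0.05)), "increasing")
})

test_that("phase is the four-quadrant angle with zero cells flagged", {
  d <- fake_decomposition(matrix(c(1 + 0i, 0 + 1i, -1 + 0i, 0 + 0i), 1))
  ph <- wavelet_phase(d)
  expect_equal(ph[1, 1:3], c(0, pi / 2, pi))
  expect_true(is.na(ph[1, 4]))
})

test_that("amplitude is the mean modulus, nonnegative and homogeneous", {
  d <- fake_decomposition(matrix(3 + 4i, 1, 10))
  expect_equal(unname(wavelet_amplitude(d)), 5)
  expect_equal(unname(wavelet_amplitude(fake_decomposition(matrix(0i, 2, 5)))), c(0, 0))

  set.seed(5)
  W <- matrix(complex(real = rnorm(60), imaginary = rnorm(60)), 3, 20)
  d <- fake_decomposition(W)
  # brute-force loop oracle: mean of element moduli per row
  oracle <- sapply(1:3, function(k) {
    s <- 0
    for (t in 1:20) s <- s + sqrt(Re(W[k, t])^2 + Im(W[k, t])^2)
    s / 20
  })
  expect_equal(unname(wavelet_amplitude(d)), oracle, tolerance = 1e-12)
  expect_equal(
    unname(wavelet_amplitude(fake_decomposition(-2 * W))),
    2 * oracle,
    tolerance = 1e-12
  )
})

test_that("band-averaged amplitude scales linearly with sinusoid amplitude", {
  n <- round(600 * fs)
  spec <- wavelet_spec(freqs = wavelet_grid(0.01, 0.1, 8))
  t <- (0:(n - 1)) / fs
  amps <- sapply(c(1, 2, 4), function(A) {
    d <- cwt_morlet(A * sin(2 * pi * 0.04 * t), fs, spec)
    band_average(wavelet_amplitude(d), spec$freqs)
  })
  expect_equal(amps[2] / amps[1], 2, tolerance = 0.01)
  expect_equal(amps[3] / amps[1], 4, tolerance = 0.01)
})

test_that("band_average matches a loop oracle and rejects empty bands", {
  freqs <- seq(0.01, 0.1, by = 0.01)
  vals <- seq_along(freqs) * 1.5
  inside <- freqs > 0.02 & freqs < 0.09
  s <- 0
  nin <- 0
  for (i in seq_along(freqs)) {
    if (inside[i]) {
      s <- s + vals[i]
      nin <- nin + 1
    }
  }
  expect_equal(band_average(vals, freqs, c(0.02, 0.09)), s / nin)
  expect_equal(band_average(rep(7, 10), freqs, c(0.02, 0.09)), 7)
  expect_equal(band_average(vals, freqs, c(0.035, 0.045)), vals[4])
  expect_error(band_average(vals, freqs, c(0.101, 0.2)), "no grid frequency")
})

test_that("cone-of-influence mask widens toward low frequencies", {
  n <- round(600 * fs)
  spec <- wavelet_spec(freqs = c(0.01, 0.1))
  d <- cwt_morlet(rnorm(n), fs, spec)
  keep <- coi_mask(d)
  expect_lt(sum(keep[1, ]), sum(keep[2, ])) # lower frequency loses more edge
  a_all <- wavelet_amplitude(d)
  a_coi <- wavelet_amplitude(d, exclude_coi = TRUE)
  expect_true(all(is.finite(a_coi)) && all(a_coi >= 0))
  expect_false(identical(a_all, a_coi))
})
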