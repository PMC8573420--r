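test_that("the default cohort writes the full 22-channel montage", {
  cfg <- cohort_config(n_subjects = 2, duration = 200, seed = 91)
  rec <- generate_recording(cfg, 1, "near")
  expect_equal(nrow(rec$samples), 22)
  expect_identical(rec$channel_labels, sprintf("CH%02d", 1:22))
  expect_equal(rec$fs, 13.33)
  expect_equal(ncol(rec$samples), round(200 * 13.33))
})

test_that("an empty signal model produces all-zero channels", {
  cfg <- cohort_config(
    n_subjects = 2, duration = 200, oscillators = list(),
    couplings = list(), drift_amplitude = 0, noise_sd = 0, seed = 92
  )
  rec <- generate_recording(cfg, 1, "prior")
  expect_true(all(rec$samples == 0))
})

test_that("generation is bit-deterministic and order-independent", {
  cfg <- cohort_config(n_subjects = 3, duration = 200, seed = 93)
  a <- generate_recording(cfg, 2, "far")
  b <- generate_recording(cfg, 2, "far")
  expect_identical(a$samples, b$samples)
  # generating another subject first must not perturb subject 2
  invisible(generate_recording(cfg, 1, "near"))
  c <- generate_recording(cfg, 2, "far")
  expect_identical(a$samples, c$samples)
  # different subject / condition gives different data
  expect_false(identical(
    a$samples,
    generate_recording(cfg, 3, "far")$samples
  ))
  expect_false(identical(
    a$samples,
    generate_recording(cfg, 2, "near")$samples
  ))
})

test_that("invalid requests are refused", {
  cfg <- cohort_config(n_subjects = 2, duration = 200, seed = 94)
  expect_error(generate_recording(cfg, 5, "near"), "out of range")
  expect_error(generate_recording(cfg, 1, "task"))
  expect_error(cohort_config(duration = 100), "two cycles")
  expect_error(coupling_spec(c("CH01", "CH01"), 0.5), "distinct")
  expect_error(coupling_spec(c("CH01", "CH02"), 0.5, band = c(0.2, 0.4)), "analysis band")
  expect_error(oscillator_spec(0.03, interval = "cardiac"), "declared interval")
  expect_error(oscillator_spec(3), "outside all six")
})

test_that("oscillator spectral mass concentrates in its declared interval", {
  fs <- 13.33
  n <- round(600 * fs)
  for (osc in list(oscillator_spec(0.035), oscillator_spec(0.09), oscillator_spec(1.1))) {
    cfg <- cohort_config(
      n_subjects = 2, duration = 600, channels = "CH01",
      oscillators = list(osc), couplings = list(),
      drift_amplitude = 0, noise_sd = 0, seed = 95
    )
    x <- generate_recording(cfg, 1, "prior")$samples[1, ]
    # periodogram-integration oracle
    sp <- stats::spec.pgram(ts(x, frequency = fs), taper = 0, detrend = FALSE, plot = FALSE)
    rng <- band_interval(osc$interval)
    mass <- sum(sp$spec[sp$freq >= rng[1] & sp$freq <= rng[2]]) / sum(sp$spec)
    expect_gt(mass, 0.9)
  }
})

test_that("full coupling with no noise locks the in-band phase difference", {
  cfg <- coupled_config(strength = 1, seed = 96, phase_lag = pi / 3)
  rec <- generate_recording(cfg, 1, "prior")
  spec <- wavelet_spec(freqs = c(0.03, 0.05))
  di <- cwt_morlet(rec$samples[1, ], rec$fs, spec, pad = "none")
  dj <- cwt_morlet(rec$samples[2, ], rec$fs, spec, pad = "none")
  dphi <- wavelet_phase(dj) - wavelet_phase(di)
  dphi <- (dphi + pi) %% (2 * pi) - pi
  expect_lt(max(abs(dphi - median(dphi))), 1e-8)
  expect_equal(median(dphi), -pi / 3, tolerance = 1e-8)
})

test_that("behavioral records implement the linear coupling model", {
  # residual sd 0 and positive slope: perfect correlation with kappa
  cfg <- cohort_config(
    n_subjects = 12, duration = 200, seed = 97,
    behavioral = list(intercept = 10, slope = 20, residual_sd = 0)
  )
  ch <- generate_cohort(cfg, recordings = FALSE)
  expect_equal(nrow(ch$behavioral), 12)
  expect_equal(cor(ch$kappa$kappa, ch$behavioral$performance_near), 1)
  expect_equal(
    ch$behavioral$performance_far,
    10 + 20 * ch$kappa$kappa
  )
  # slope 0: performance carries no kappa information
  cfg0 <- cohort_config(
    n_subjects = 40, duration = 200, seed = 98,
    behavioral = list(intercept = 10, slope = 0, residual_sd = 5)
  )
  ch0 <- generate_cohort(cfg0, recordings = FALSE)
  expect_lt(abs(cor(ch0$kappa$kappa, ch0$behavioral$performance_near)), 0.5)
  expect_equal(sd(ch0$behavioral$performance_far - 10) > 0, TRUE)
})

test_that("a cohort round-trips through its on-disk layout", {
  cfg <- cohort_config(n_subjects = 2, duration = 200, seed = 99)
  ch <- generate_cohort(cfg, conditions = "near")
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  expect_true(file.exists(file.path(dir, "S01_near.csv")))
  expect_true(file.exists(file.path(dir, "behavioral.csv")))
  back <- read_recording(file.path(dir, "S02_near.csv"))
  expect_identical(back$samples, ch$recordings$near[[2]]$samples)
  kap <- readr::read_csv(file.path(dir, "kappa.csv"), show_col_types = FALSE)
  expect_equal(kap$kappa, ch$kappa$kappa)
})
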