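#' Specify one band-limited physiological oscillator
#'
#' Synthetic hemodynamic rhythms are realized as Gaussian white noise
#' spectrally confined to `center * (1 - fbw)` .. `center * (1 + fbw)` Hz —
#' realistic non-sinusoidal oscillations rather than pure tones. Each
#' oscillator targets one of the six physiological intervals and its center
#' frequency must lie inside that interval.
#'
#' @param center center frequency, Hz.
#' @param fbw fractional bandwidth in (0, 1).
#' @param amplitude target standard deviation of the realized component
#'   (signal units, >= 0).
#' @param interval roman numeral or physiological name of the target
#'   interval; inferred from `center` when omitted.
#' @return an `oscillator_spec` list.
#' @export
oscillator_spec <- function(center, fbw = 0.3, amplitude = 1, interval = NULL) {
  stopifnot(center > 0, fbw > 0, fbw < 1, amplitude >= 0)
  b <- fnirs_bands()
  if (is.null(interval)) {
    hit <- which(center >= b$lo & center < b$hi)
    if (!length(hit)) stop("center frequency outside all six intervals", call. = FALSE)
    interval <- b$interval[hit[1]]
  } else {
    rng <- band_interval(interval)
    if (center < rng[1] || center > rng[2]) {
      stop("center frequency outside its declared interval", call. = FALSE)
    }
    i <- match(interval, b$interval)
    if (is.na(i)) i <- match(interval, b$name)
    interval <- b$interval[i]
  }
  structure(
    list(center = center, fbw = fbw, amplitude = amplitude, interval = interval),
    class = "oscillator_spec"
  )
}

#' Specify a planted phase coupling between two channels
#'
#' Ground truth for coherence recovery: within `band`, the two channels share
#' a common band-limited source mixed with amplitude weight `sqrt(strength)`
#' against independent in-band sources with weight `sqrt(1 - strength)`, so
#' the shared fraction of in-band variance equals `strength` (kappa) exactly
#' and total in-band power is constant across kappa; the second channel
#' receives the shared source at a constant phase lag. Expected coherence
#' rises monotonically with `strength`: kappa = 0 gives independent channels,
#' kappa = 1 a constant in-band phase difference.
#'
#' @param pair character length-2, the two (distinct) channel labels.
#' @param strength coupling strength kappa in `[0, 1]`.
#' @param phase_lag constant phase lag in radians applied to the second
#'   channel's shared component.
#' @param band coupling band `c(lo, hi)` in Hz, inside the 0.01–0.1 Hz
#'   analysis band.
#' @param amplitude standard-deviation scale of the coupled component.
#' @return a `coupling_spec` list.
#' @export
coupling_spec <- function(pair, strength, phase_lag = 0,
                          band = c(0.02, 0.08), amplitude = 1) {
  stopifnot(length(pair) == 2, strength >= 0, strength <= 1, amplitude >= 0)
  if (pair[1] == pair[2]) stop("coupling requires two distinct channels", call. = FALSE)
  ab <- analysis_band()
  if (band[1] < ab[1] || band[2] > ab[2] || band[1] >= band[2]) {
    stop("coupling band must lie within the 0.01-0.1 Hz analysis band", call. = FALSE)
  }
  structure(
    list(
      pair = pair, strength = strength, phase_lag = phase_lag,
      band = band, amplitude = amplitude
    ),
    class = "coupling_spec"
  )
}

default_oscillators <- function() {
  list(
    oscillator_spec(1.1, 0.3, 0.3), # cardiac
    oscillator_spec(0.30, 0.3, 0.3), # respiration
    oscillator_spec(0.09, 0.3, 0.5), # myogenic
    oscillator_spec(0.035, 0.3, 1.0), # neurogenic
    oscillator_spec(0.014, 0.3, 0.5) # endothelial metabolic
  )
}

default_couplings <- function() {
  list(
    prior = list(),
    near = list(
      coupling_spec(c("CH08", "CH15"), 0.7),
      coupling_spec(c("CH16", "CH22"), 0.5)
    ),
    far = list(
      coupling_spec(c("CH08", "CH15"), 0.4),
      coupling_spec(c("CH16", "CH22"), 0.3)
    )
  )
}

#' Synthetic cohort configuration
#'
#' Defaults mirror the study conditions the pipeline targets: 31 subjects,
#' 22-channel montage sampled at 13.33 Hz, 10-minute (600 s) resting
#' segments per condition, band-limited oscillators in five of the six
#' physiological intervals, slow half-cosine drift and broadband noise.
#' Per-subject coupling scale kappa is drawn once per subject (truncated
#' normal) and multiplies every planted coupling strength; behavioral
#' performance is `intercept + slope * kappa + N(0, residual_sd)`, so the
#' planted population correlation between kappa and performance is
#' `slope * sd(kappa) / sqrt(slope^2 * var(kappa) + residual_sd^2)`.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param fs sampling rate, Hz.
#' @param duration segment length, seconds; must span at least two cycles of
#'   the lowest analysis frequency (0.01 Hz).
#' @param channels montage channel labels.
#' @param oscillators list of [oscillator_spec()].
#' @param couplings named list (`prior`, `near`, `far`) of lists of
#'   [coupling_spec()].
#' @param drift_amplitude amplitude of the half-cosine drift (period twice
#'   the recording, exercising the DCT detrend).
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param behavioral list `(intercept, slope, residual_sd)` linking kappa to
#'   near/far performance.
#' @param subject_kappa list `(mean, sd)` of the per-subject kappa draw
#'   (clamped to `[0, 1]`).
#' @param seed root seed; every draw flows from it via named substreams.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 31, fs = 13.33, duration = 600,
                          channels = montage_labels(),
                          oscillators = default_oscillators(),
                          couplings = default_couplings(),
                          drift_amplitude = 2, noise_sd = 0.5,
                          behavioral = list(intercept = 50, slope = 30, residual_sd = 8),
                          subject_kappa = list(mean = 0.6, sd = 0.15),
                          seed = 1L) {
  stopifnot(n_subjects >= 2, fs > 0, duration > 0)
  if (duration < 2 / analysis_band()[1]) {
    stop("duration must span at least two cycles of the lowest analysis frequency",
      call. = FALSE
    )
  }
  for (cond in names(couplings)) {
    for (cp in couplings[[cond]]) {
      if (!all(cp$pair %in% channels)) {
        stop("coupling references a channel outside the montage", call. = FALSE)
      }
    }
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), fs = fs, duration = duration,
      channels = channels, oscillators = oscillators, couplings = couplings,
      drift_amplitude = drift_amplitude, noise_sd = noise_sd,
      behavioral = behavioral, subject_kappa = subject_kappa,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Per-subject coupling scale
#'
#' The subject's kappa draw, reproducible from `(seed, subject_index)` alone.
#'
#' @param config a [cohort_config()].
#' @param subject_index 1-based subject index.
#' @return scalar kappa in `[0, 1]`.
#' @export
subject_kappa <- function(config, subject_index) {
  with_seed(
    substream_seed(config$seed, "kappa", subject_index),
    {
      k <- stats::rnorm(1, config$subject_kappa$mean, config$subject_kappa$sd)
      min(max(k, 0), 1)
    }
  )
}

#' Generate one synthetic recording
#'
#' Each channel is the sum of independent realizations of every configured
#' oscillator (random phase per channel), plus — for channels named in a
#' coupling of this condition — a mixed coupled component, plus half-cosine
#' drift and white Gaussian noise. Deterministic given
#' `(seed, subject_index, condition)`, independent of generation order.
#'
#' @param config a [cohort_config()].
#' @param subject_index 1-based subject index (`<= n_subjects`).
#' @param condition `"prior"`, `"near"` or `"far"`.
#' @return an `fnirs_recording`.
#' @export
generate_recording <- function(config, subject_index, condition) {
  stopifnot(inherits(config, "cohort_config"))
  condition <- match.arg(condition, c("prior", "near", "far"))
  if (subject_index < 1 || subject_index > config$n_subjects) {
    stop("subject_index out of range", call. = FALSE)
  }
  fs <- config$fs
  n <- round(config$duration * fs)
  nch <- length(config$channels)
  kappa_s <- subject_kappa(config, subject_index)
  x <- with_seed(
    substream_seed(config$seed, "rec", subject_index, condition),
    {
      x <- matrix(0, nch, n)
      for (osc in config$oscillators) {
        lo <- osc$center * (1 - osc$fbw)
        hi <- osc$center * (1 + osc$fbw)
        if (osc$amplitude > 0) {
          for (c in seq_len(nch)) {
            x[c, ] <- x[c, ] + band_noise(n, fs, lo, hi, sd = osc$amplitude)
          }
        }
      }
      for (cp in config$couplings[[condition]] %||% list()) {
        k <- cp$strength * kappa_s
        i <- match(cp$pair[1], config$channels)
        j <- match(cp$pair[2], config$channels)
        s <- band_noise(n, fs, cp$band[1], cp$band[2], sd = 1)
        ei <- band_noise(n, fs, cp$band[1], cp$band[2], sd = 1)
        ej <- band_noise(n, fs, cp$band[1], cp$band[2], sd = 1)
        x[i, ] <- x[i, ] + cp$amplitude * (sqrt(k) * s + sqrt(1 - k) * ei)
        x[j, ] <- x[j, ] +
          cp$amplitude * (sqrt(k) * phase_shift(s, cp$phase_lag) + sqrt(1 - k) * ej)
      }
      if (config$drift_amplitude != 0) {
        t <- (seq_len(n) - 1) / fs
        drift <- config$drift_amplitude * cos(pi * t / config$duration)
        x <- sweep(x, 2, drift, "+")
      }
      if (config$noise_sd > 0) {
        x <- x + matrix(stats::rnorm(nch * n, 0, config$noise_sd), nch, n)
      }
      x
    }
  )
  recording(x, fs, config$channels,
    subject_id = sprintf("S%02d", subject_index), condition = condition
  )
}

#' Generate a full synthetic cohort
#'
#' Recordings for every subject and requested condition plus one behavioral
#' record per subject. Performance under each condition is
#' `intercept + slope * kappa + N(0, residual_sd)`; the prior cognitive score
#' is an independent standard-normal draw (it drives the extreme-group split,
#' not the planted correlation).
#'
#' @param config a [cohort_config()].
#' @param conditions conditions to realize.
#' @param recordings generate the signal matrices? `FALSE` returns behavioral
#'   records and kappa only (the statistics stage needs nothing else).
#' @return list with `recordings` (named list per condition of lists of
#'   `fnirs_recording`, or `NULL`), `behavioral` (tibble: subject_id,
#'   prior_score, performance_near, performance_far) and `kappa` (tibble:
#'   subject_id, kappa — the planted ground truth).
#' @export
generate_cohort <- function(config, conditions = c("prior", "near", "far"),
                            recordings = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  ns <- config$n_subjects
  kap <- vapply(seq_len(ns), function(s) subject_kappa(config, s), numeric(1))
  beh <- lapply(seq_len(ns), function(s) {
    with_seed(substream_seed(config$seed, "behav", s), {
      b <- config$behavioral
      tibble::tibble(
        subject_id = sprintf("S%02d", s),
        prior_score = stats::rnorm(1),
        performance_near = b$intercept + b$slope * kap[s] +
          stats::rnorm(1, 0, b$residual_sd),
        performance_far = b$intercept + b$slope * kap[s] +
          stats::rnorm(1, 0, b$residual_sd)
      )
    })
  })
  recs <- NULL
  if (recordings) {
    recs <- lapply(stats::setNames(conditions, conditions), function(cond) {
      lapply(seq_len(ns), function(s) generate_recording(config, s, cond))
    })
  }
  list(
    recordings = recs,
    behavioral = dplyr::bind_rows(beh),
    kappa = tibble::tibble(subject_id = sprintf("S%02d", seq_len(ns)), kappa = kap)
  )
}

#' Write a cohort to disk
#'
#' Recordings in the CSV + JSON sidecar dialect (one file per subject and
#' condition), the behavioral table as `behavioral.csv` and the ground-truth
#' kappa table as `kappa.csv`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cohort$recordings)) {
    for (cond in names(cohort$recordings)) {
      for (rec in cohort$recordings[[cond]]) {
        write_recording(rec, file.path(dir, sprintf("%s_%s.csv", rec$subject_id, cond)))
      }
    }
  }
  readr::write_csv(cohort$behavioral, file.path(dir, "behavioral.csv"), progress = FALSE)
  readr::write_csv(cohort$kappa, file.path(dir, "kappa.csv"), progress = FALSE)
  invisible(dir)
}
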