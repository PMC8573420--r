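#' Wavelet phase coherence between two phase arrays
#'
#' For each frequency, the modulus of the time-averaged unit phasor of the
#' phase difference:
#' `WPCO(w_k) = sqrt( mean_n(cos dphi)^2 + mean_n(sin dphi)^2 )` with
#' `dphi = phases_j - phases_i`. Equals 1 when the phase difference is
#' constant over the whole series (complete coherence) and tends to 0 for
#' unrelated phases; always in `[0, 1]`.
#'
#' @param phases_i,phases_j numeric matrices (frequencies x time) or vectors
#'   of equal shape, phases in radians.
#' @return numeric vector, one coherence per frequency row.
#' @export
wpco <- function(phases_i, phases_j) {
  if (is.null(dim(phases_i))) phases_i <- matrix(phases_i, nrow = 1)
  if (is.null(dim(phases_j))) phases_j <- matrix(phases_j, nrow = 1)
  if (!identical(dim(phases_i), dim(phases_j))) {
    stop("phase arrays must have identical shape", call. = FALSE)
  }
  dphi <- phases_j - phases_i
  sqrt(rowMeans(cos(dphi))^2 + rowMeans(sin(dphi))^2)
}

#' Surrogate validity test for a coherence value
#'
#' A coherence estimate is accepted as significant only if it exceeds the
#' mean plus twice the standard deviation (sample, n-1 denominator) of the
#' coherence obtained from the surrogate ensemble; raw wavelet phase
#' coherence is otherwise inflated at low frequencies, where a finite series
#' holds few oscillation cycles.
#'
#' @param original scalar coherence of the original pair.
#' @param surrogates numeric vector of surrogate coherences, length >= 2.
#' @return list with `valid` (logical; strict inequality, a value exactly at
#'   the threshold is invalid), `margin` (`original - (mean + 2*sd)`),
#'   `surrogate_mean`, `surrogate_sd`.
#' @export
wpco_validity <- function(original, surrogates) {
  m <- length(surrogates)
  if (m < 2) stop("at least 2 surrogates needed (SD undefined)", call. = FALSE)
  mu <- mean(surrogates)
  sdev <- stats::sd(surrogates)
  margin <- original - (mu + 2 * sdev)
  list(valid = margin > 0, margin = margin, surrogate_mean = mu, surrogate_sd = sdev)
}

#' All unordered channel pairs of a montage
#'
#' @param labels channel label vector (or an integer count, expanded to
#'   `CH01`...).
#' @return tibble with columns `ch_i`, `ch_j`, canonicalized so `ch_i`
#'   precedes `ch_j` in montage order; `C(n, 2)` rows.
#' @export
channel_pairs <- function(labels) {
  if (is.numeric(labels) && length(labels) == 1) {
    labels <- sprintf("CH%02d", seq_len(labels))
  }
  idx <- utils::combn(length(labels), 2)
  tibble::tibble(ch_i = labels[idx[1, ]], ch_j = labels[idx[2, ]])
}

# Unit phasor array (nfreq x time x channels) of a recording against a
# precomputed filter bank. Zero-modulus cells (no defined phase) map to a
# zero phasor so they contribute nothing to the time average.
unit_phasors <- function(samples, bank, n, spec, fs) {
  C <- nrow(samples)
  arr <- array(0i, c(length(spec$freqs), n, C))
  for (c in seq_len(C)) {
    W <- cwt_with_bank(samples[c, ], bank, n, spec, fs)$coefficients
    mod <- Mod(W)
    U <- W
    nz <- mod > 0
    U[nz] <- U[nz] / mod[nz]
    U[!nz] <- 0i
    arr[, , c] <- U
  }
  arr
}

# Cross-coherence matrices |t(Conj(U_a)) %*% U_b| / n for every frequency:
# returns nfreq x C x C array of WPCO values (diagonal of the symmetric case
# is exactly 1 wherever phases are defined everywhere).
cross_wpco <- function(arr_a, arr_b) {
  nf <- dim(arr_a)[1]
  n <- dim(arr_a)[2]
  C <- dim(arr_a)[3]
  out <- array(NA_real_, c(nf, C, C))
  for (k in seq_len(nf)) {
    Ua <- matrix(arr_a[k, , ], n, C)
    Ub <- matrix(arr_b[k, , ], n, C)
    out[k, , ] <- Mod(crossprod(Conj(Ua), Ub)) / n
  }
  out
}

#' Pairwise wavelet phase coherence with surrogate validity over a montage
#'
#' For every unordered channel pair of a (preprocessed) recording: decompose
#' both channels with the complex Morlet wavelet, compute per-frequency WPCO
#' and its mean over the analysis band, compare against an ensemble of `m`
#' AAFT surrogate realizations, and flag validity by the mean + 2 SD rule.
#'
#' Surrogate realization k replaces each channel by its own independently
#' seeded AAFT surrogate; pair (i, j) is compared between realization k of i
#' and realization k of j (`surrogate_mode = "both"`, the default, destroys
#' the phase relation symmetrically) or between the original i and surrogate
#' j (`"one"`). The whole ensemble is reproducible from `seed` via named
#' substreams, independent of evaluation order.
#'
#' @param rec an `fnirs_recording` (preprocess first; the surrogate null
#'   assumes detrended, roughly stationary channels).
#' @param m surrogate count (default 100).
#' @param seed integer root seed for the surrogate ensemble.
#' @param band analysis band `c(lo, hi)` in Hz.
#' @param spec optional [wavelet_spec()]; default a log grid spanning `band`
#'   at `voices` voices per octave.
#' @param voices voices per octave for the default grid.
#' @param surrogate_mode `"both"` or `"one"` (see Details).
#' @param decimate integer factor; if > 1 the recording is first reduced with
#'   [decimate_recording()] (zero-phase), cutting transform cost for slow
#'   bands far below Nyquist.
#' @return A tibble with one row per unordered pair: `ch_i`, `ch_j`,
#'   `band_wpco`, `surrogate_mean`, `surrogate_sd`, `margin`, `valid`.
#'   Attributes: `freqs` (grid), `freq_wpco` and `freq_valid` (per-frequency
#'   matrices, frequencies x pairs), `band`, `m`, `surrogate_mode`, `seed`,
#'   `subject_id`, `condition`.
#' @export
pair_matrix <- function(rec, m = 100, seed = 1, band = analysis_band(),
                        spec = NULL, voices = 8,
                        surrogate_mode = c("both", "one"), decimate = 1) {
  stopifnot(inherits(rec, "fnirs_recording"), m >= 2)
  surrogate_mode <- match.arg(surrogate_mode)
  if (decimate > 1) rec <- decimate_recording(rec, decimate)
  fs <- rec$fs
  n <- ncol(rec$samples)
  C <- nrow(rec$samples)
  if (is.null(spec)) {
    spec <- wavelet_spec(freqs = wavelet_grid(band[1], band[2], voices))
  }
  if (max(spec$freqs) >= fs / 2) {
    stop("grid frequencies must lie below the Nyquist frequency", call. = FALSE)
  }
  if (n < 2 * fs / min(spec$freqs)) {
    stop("recording shorter than two cycles of the lowest grid frequency",
      call. = FALSE
    )
  }
  nf <- length(spec$freqs)
  inband <- spec$freqs > band[1] & spec$freqs < band[2]
  if (!any(inband)) stop("no grid frequency strictly inside the band", call. = FALSE)
  M <- next_pow2(2L * n)
  bank <- morlet_bank(M, fs, spec)

  orig <- unit_phasors(rec$samples, bank, n, spec, fs)
  w_orig <- cross_wpco(orig, orig) # nf x C x C
  band_orig <- apply(w_orig[inband, , , drop = FALSE], c(2, 3), mean)

  sum_b <- matrix(0, C, C)
  sumsq_b <- matrix(0, C, C)
  sum_f <- array(0, c(nf, C, C))
  sumsq_f <- array(0, c(nf, C, C))
  for (k in seq_len(m)) {
    surr <- rec$samples
    for (c in seq_len(C)) {
      surr[c, ] <- aaft_surrogate(rec$samples[c, ],
        seed = substream_seed(seed, "aaft", c, k)
      )
    }
    arr_s <- unit_phasors(surr, bank, n, spec, fs)
    w_s <- if (surrogate_mode == "both") {
      cross_wpco(arr_s, arr_s)
    } else {
      cross_wpco(orig, arr_s)
    }
    b_s <- apply(w_s[inband, , , drop = FALSE], c(2, 3), mean)
    sum_b <- sum_b + b_s
    sumsq_b <- sumsq_b + b_s^2
    sum_f <- sum_f + w_s
    sumsq_f <- sumsq_f + w_s^2
  }
  mu_b <- sum_b / m
  sd_b <- sqrt(pmax(sumsq_b - m * mu_b^2, 0) / (m - 1))
  mu_f <- sum_f / m
  sd_f <- sqrt(pmax(sumsq_f - m * mu_f^2, 0) / (m - 1))

  pairs <- channel_pairs(rec$channel_labels)
  ii <- match(pairs$ch_i, rec$channel_labels)
  jj <- match(pairs$ch_j, rec$channel_labels)
  lin <- cbind(ii, jj)
  out <- pairs
  out$band_wpco <- band_orig[lin]
  out$surrogate_mean <- mu_b[lin]
  out$surrogate_sd <- sd_b[lin]
  out$margin <- out$band_wpco - (out$surrogate_mean + 2 * out$surrogate_sd)
  out$valid <- out$margin > 0

  np <- nrow(pairs)
  freq_wpco <- matrix(NA_real_, nf, np)
  freq_valid <- matrix(NA, nf, np)
  for (p in seq_len(np)) {
    freq_wpco[, p] <- w_orig[, ii[p], jj[p]]
    freq_valid[, p] <- w_orig[, ii[p], jj[p]] -
      (mu_f[, ii[p], jj[p]] + 2 * sd_f[, ii[p], jj[p]]) > 0
  }
  structure(out,
    freqs = spec$freqs, freq_wpco = freq_wpco, freq_valid = freq_valid,
    band = band, m = m, surrogate_mode = surrogate_mode, seed = seed,
    subject_id = rec$subject_id, condition = rec$condition,
    class = c("wpco_pairs", class(out))
  )
}

#' Band wavelet phase coherence of one channel pair, no surrogates
#'
#' Lightweight path used for parameter-recovery experiments: decompose two
#' channels, compute per-frequency WPCO and average over the band.
#'
#' @inheritParams pair_matrix
#' @param i,j channel labels or indices.
#' @param pad padding mode passed to [cwt_morlet()].
#' @return scalar band WPCO.
#' @export
band_wpco <- function(rec, i, j, band = analysis_band(), spec = NULL,
                      voices = 8, decimate = 1, pad = "zero") {
  stopifnot(inherits(rec, "fnirs_recording"))
  if (decimate > 1) rec <- decimate_recording(rec, decimate)
  if (is.numeric(i)) i <- rec$channel_labels[i]
  if (is.numeric(j)) j <- rec$channel_labels[j]
  if (is.null(spec)) {
    spec <- wavelet_spec(freqs = wavelet_grid(band[1], band[2], voices))
  }
  di <- cwt_morlet(rec$samples[i, ], rec$fs, spec, pad = pad)
  dj <- cwt_morlet(rec$samples[j, ], rec$fs, spec, pad = pad)
  w <- wpco(wavelet_phase(di), wavelet_phase(dj))
  band_average(w, spec$freqs, band)
}

#' Write a pair-coherence table and its run manifest
#'
#' Long-format CSV (subject, condition, ch_i, ch_j, band_wpco,
#' surrogate_mean, surrogate_sd, margin, valid) plus a JSON manifest
#' recording the band, surrogate count, mode and seed.
#'
#' @param pairs a `wpco_pairs` tibble from [pair_matrix()].
#' @param path CSV output path (manifest at the same path with `.json`).
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  df <- tibble::tibble(
    subject = attr(pairs, "subject_id"),
    condition = attr(pairs, "condition"),
    pairs[, c(
      "ch_i", "ch_j", "band_wpco", "surrogate_mean",
      "surrogate_sd", "margin", "valid"
    )]
  )
  readr::write_csv(df, path, progress = FALSE)
  manifest <- list(
    band = attr(pairs, "band"), m = attr(pairs, "m"),
    surrogate_mode = attr(pairs, "surrogate_mode"),
    seed = attr(pairs, "seed"), freqs = attr(pairs, "freqs")
  )
  jsonlite::write_json(manifest, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
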