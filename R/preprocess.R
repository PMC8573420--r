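#' Canonical double-gamma hemodynamic response kernel
#'
#' The conventional SPM shape: a gamma density peaking about 5 s after
#' stimulus minus a later undershoot gamma (shape 16) scaled by 1/6, sampled
#' on 0–32 s at the recording rate and normalized to unit sum so filtering
#' preserves the DC level.
#'
#' @param fs sampling rate, Hz.
#' @param support kernel support in seconds (default 32).
#' @return numeric vector summing to 1.
#' @export
hrf_kernel <- function(fs, support = 32) {
  t <- seq(0, support, by = 1 / fs)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / sum(h)
}

#' Smooth a recording with the canonical HRF low-pass filter
#'
#' Each channel is convolved with the unit-sum double-gamma kernel of
#' [hrf_kernel()]. The convolution is single-pass with reflection pre-padding
#' of one kernel length, so there is no startup transient and a unit impulse
#' maps to the kernel placed at the impulse. The hemodynamic delay this
#' introduces is identical across channels and therefore cancels in any
#' between-channel phase difference.
#'
#' @param rec an `fnirs_recording`.
#' @param support kernel support, seconds.
#' @return the filtered `fnirs_recording` (same shape, labels, rate).
#' @export
hrf_lowpass <- function(rec, support = 32) {
  stopifnot(inherits(rec, "fnirs_recording"))
  h <- hrf_kernel(rec$fs, support)
  L <- length(h)
  n <- ncol(rec$samples)
  if (n < L) stop("recording shorter than the HRF kernel", call. = FALSE)
  out <- t(apply(rec$samples, 1, function(x) {
    pad <- c(rev(x[seq_len(L - 1)]), x) # reflect one kernel length
    y <- stats::filter(pad, h, method = "convolution", sides = 1)
    as.numeric(y[L:(L + n - 1)])
  }))
  rec$samples <- out
  rownames(rec$samples) <- rec$channel_labels
  rec
}

# DCT-II basis vector k on n points (k = 0 is the constant)
dct_basis <- function(n, k) cos(pi * (seq_len(n) - 0.5) * k / n)

#' High-pass detrending by discrete cosine transform projection
#'
#' Projects out of each channel the DCT-II basis functions whose period
#' exceeds `cutoff_period` (basis function k has period `2 * duration / k`;
#' the constant term k = 0 is always removed, so the output is zero-mean per
#' channel). This is the conventional fMRI/fNIRS high-pass: slow scanner and
#' physiological drift lives in the leading cosines.
#'
#' The removed basis is orthogonal, so the operator is an idempotent linear
#' projection: applying it twice equals applying it once.
#'
#' @param rec an `fnirs_recording`.
#' @param cutoff_period high-pass cutoff in seconds (default 128, the
#'   conventional fMRI value). Must exceed two sample intervals.
#' @return the detrended `fnirs_recording`.
#' @export
dct_detrend <- function(rec, cutoff_period = 128) {
  stopifnot(inherits(rec, "fnirs_recording"))
  if (cutoff_period <= 2 / rec$fs) {
    stop("`cutoff_period` must exceed two sample intervals", call. = FALSE)
  }
  n <- ncol(rec$samples)
  dur <- n / rec$fs
  if (cutoff_period > dur) {
    warning("cutoff_period exceeds the recording duration; only the mean is removed")
  }
  # remove k with period 2*dur/k > cutoff  <=>  k < 2*dur/cutoff
  kmax <- ceiling(2 * dur / cutoff_period) - 1
  out <- rec$samples - rowMeans(rec$samples) # k = 0
  if (kmax >= 1) {
    for (k in seq_len(kmax)) {
      ck <- dct_basis(n, k)
      beta <- (out %*% ck) / (n / 2) # basis norm^2 = n/2 for k > 0
      out <- out - beta %*% t(ck)
    }
  }
  rec$samples <- out
  rownames(rec$samples) <- rec$channel_labels
  rec
}

#' Full signal conditioning for a recording
#'
#' Composes the HRF low-pass smoothing and the DCT high-pass detrending in a
#' configurable order (default: low-pass first, then detrend, so the detrend
#' also removes any slow component the smoothing leaves).
#'
#' @param rec an `fnirs_recording`.
#' @param cutoff_period DCT high-pass cutoff, seconds.
#' @param hrf apply the HRF low-pass? Whether the smoothing step belongs on
#'   resting-state segments is a pipeline choice; it is on by default and
#'   switchable here.
#' @param order `"lowpass_first"` (default) or `"detrend_first"`.
#' @param verbose log the steps applied.
#' @return the conditioned `fnirs_recording`.
#' @export
preprocess <- function(rec, cutoff_period = 128, hrf = TRUE,
                       order = c("lowpass_first", "detrend_first"),
                       verbose = FALSE) {
  order <- match.arg(order)
  steps <- if (order == "lowpass_first") c("lp", "hp") else c("hp", "lp")
  for (s in steps) {
    if (s == "lp" && hrf) {
      rec <- hrf_lowpass(rec)
      if (verbose) message("applied HRF low-pass")
    }
    if (s == "hp") {
      rec <- dct_detrend(rec, cutoff_period)
      if (verbose) message("applied DCT detrend (cutoff ", cutoff_period, " s)")
    }
  }
  rec
}
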