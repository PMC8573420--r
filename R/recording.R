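#' Construct a multichannel fNIRS recording
#'
#' The pipeline's universal currency: a labeled (channels x time) matrix of
#' oxyhemoglobin concentration changes with its sampling rate, subject id and
#' condition tag.
#'
#' @param samples numeric matrix, channels x time; all values finite.
#' @param fs sampling rate in Hz (the montage's native rate is 13.33 Hz).
#' @param channel_labels character vector, one label per row of `samples`;
#'   defaults to `CH01`, `CH02`, ... Labels must be unique.
#' @param subject_id subject identifier.
#' @param condition condition tag, one of `"prior"`, `"near"`, `"far"`.
#' @return An object of class `fnirs_recording`.
#' @export
recording <- function(samples, fs, channel_labels = NULL,
                      subject_id = "S01", condition = "prior") {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("CH%02d", seq_len(nrow(samples)))
  }
  condition <- match.arg(condition, c("prior", "near", "far"))
  if (length(channel_labels) != nrow(samples)) {
    stop("one channel label per row of `samples` required", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  if (!all(is.finite(samples))) stop("samples must be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive scalar (Hz)", call. = FALSE)
  }
  rownames(samples) <- channel_labels
  structure(
    list(
      subject_id = subject_id, condition = condition,
      channel_labels = channel_labels, fs = fs, samples = samples
    ),
    class = "fnirs_recording"
  )
}

#' @export
print.fnirs_recording <- function(x, ...) {
  cat(sprintf(
    "<fnirs_recording> subject %s, condition %s\n  %d channels x %d samples at %.4g Hz (%.1f s)\n",
    x$subject_id, x$condition, nrow(x$samples), ncol(x$samples), x$fs,
    ncol(x$samples) / x$fs
  ))
  invisible(x)
}

#' Number of samples and duration helpers
#' @param rec an `fnirs_recording`.
#' @return `n_samples()`: integer sample count; `duration()`: seconds.
#' @export
n_samples <- function(rec) ncol(rec$samples)

#' @rdname n_samples
#' @export
duration <- function(rec) ncol(rec$samples) / rec$fs

#' Reduce a recording's sampling rate
#'
#' Zero-phase spectral low-pass (brick wall at 0.4 of the target rate)
#' followed by subsampling. For analyses confined to slow bands this cuts
#' wavelet-transform cost by the decimation factor without touching in-band
#' instantaneous phase.
#'
#' @param rec an `fnirs_recording`.
#' @param q integer decimation factor (>= 1; 1 returns the input).
#' @return an `fnirs_recording` at rate `fs / q`.
#' @export
decimate_recording <- function(rec, q) {
  stopifnot(inherits(rec, "fnirs_recording"))
  q <- as.integer(q)
  if (q <= 1L) return(rec)
  out <- t(apply(rec$samples, 1, fft_decimate, q = q, fs = rec$fs))
  recording(out, rec$fs / q, rec$channel_labels, rec$subject_id, rec$condition)
}

#' Write / read a recording as wide CSV with a JSON sidecar
#'
#' The on-disk dialect is a wide CSV whose first column is `time_s` followed
#' by one column per channel, plus a JSON sidecar (same path with `.json`
#' extension) holding `subject_id`, `condition`, `fs_hz`, `units` and
#' `channel_labels`. Finite values round-trip bit-exactly.
#'
#' @param rec an `fnirs_recording`.
#' @param path CSV file path (sidecar derived by swapping the extension).
#' @param units concentration units string recorded in the sidecar.
#' @return `write_recording()`: `path`, invisibly. `read_recording()`: an
#'   `fnirs_recording`.
#' @export
write_recording <- function(rec, path, units = "a.u.") {
  stopifnot(inherits(rec, "fnirs_recording"))
  df <- data.frame(
    time_s = (seq_len(ncol(rec$samples)) - 1) / rec$fs,
    t(rec$samples),
    check.names = FALSE
  )
  # 17 significant digits: doubles survive the text round trip bit-exactly
  df[] <- lapply(df, function(col) sprintf("%.17g", col))
  readr::write_csv(df, path, progress = FALSE)
  sidecar <- list(
    subject_id = rec$subject_id, condition = rec$condition,
    fs_hz = rec$fs, units = units, channel_labels = rec$channel_labels
  )
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  # parse as text, convert with base strtod: correctly rounded, so the
  # %.17g writer round-trips doubles bit-exactly
  df <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  df[] <- lapply(df, as.numeric)
  if (names(df)[1] != "time_s") stop("first column must be `time_s`", call. = FALSE)
  tm <- df$time_s
  if (length(tm) > 1 && any(diff(tm) <= 0)) {
    stop("`time_s` must be strictly increasing", call. = FALSE)
  }
  labels <- meta$channel_labels
  if (!setequal(names(df)[-1], labels)) {
    stop("CSV channel columns do not match sidecar `channel_labels`", call. = FALSE)
  }
  samples <- t(as.matrix(df[, labels, drop = FALSE]))
  recording(samples, meta$fs_hz, labels, meta$subject_id, meta$condition)
}
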