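#' Physiological frequency intervals of the blood-oxygen signal
#'
#' Spontaneous hemodynamic oscillations are conventionally partitioned into
#' six contiguous frequency intervals, each tied to a physiological source:
#' cardiac activity, respiration, myogenic, neurogenic, endothelial metabolic
#' and endothelial activity. Resting-state connectivity analysis of slow
#' prefrontal oscillations concentrates on 0.01–0.1 Hz, which spans the
#' neurogenic interval and the lower myogenic range.
#'
#' @return A tibble with columns `interval` (roman numeral I–VI), `name`
#'   (physiological source), `lo` and `hi` (bounds in Hz).
#' @seealso [analysis_band()]
#' @export
#' @examples
#' fnirs_bands()
fnirs_bands <- function() {
  tibble::tibble(
    interval = c("I", "II", "III", "IV", "V", "VI"),
    name = c(
      "cardiac", "respiration", "myogenic", "neurogenic",
      "endothelial metabolic", "endothelial"
    ),
    lo = c(0.6, 0.145, 0.052, 0.021, 0.0095, 0.0005),
    hi = c(2.0, 0.6, 0.145, 0.052, 0.021, 0.0095)
  )
}

#' The slow-oscillation analysis band
#'
#' The frequency interval over which connectivity is evaluated:
#' 0.01–0.1 Hz.
#'
#' @return numeric length-2 vector `c(lo, hi)` in Hz.
#' @export
analysis_band <- function() c(0.01, 0.1)

#' Look up one physiological interval by roman numeral or name
#'
#' @param which interval label (`"I"`..`"VI"`) or physiological name
#'   (e.g. `"neurogenic"`).
#' @return numeric length-2 vector `c(lo, hi)` in Hz.
#' @export
band_interval <- function(which) {
  b <- fnirs_bands()
  i <- match(which, b$interval)
  if (is.na(i)) i <- match(which, b$name)
  if (is.na(i)) stop("unknown frequency interval: ", which, call. = FALSE)
  c(b$lo[i], b$hi[i])
}
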