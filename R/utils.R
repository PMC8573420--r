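#' @keywords internal
"_PACKAGE"

#' Derive a reproducible substream seed
#'
#' Mixes a root seed with an arbitrary sequence of integer or character tags
#' (stage name, subject index, channel, surrogate index, ...) into a single
#' 31-bit seed. Used so that every stochastic stage of the pipeline draws from
#' a named substream of one root seed, independent of generation order.
#'
#' @param root integer root seed.
#' @param ... integer or character tags identifying the substream.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(root, ...) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime; all arithmetic exact in doubles
  h <- as.double(root) %% m
  for (p in list(...)) {
    if (is.character(p)) {
      codes <- utf8ToInt(p)
      p <- sum(codes * seq_along(codes))
    }
    h <- (h * 69069 + as.double(p) + 1) %% m
  }
  as.integer(h)
}

# Evaluate an expression with a locally scoped RNG state so library code does
# not clobber the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# next power of two >= n
next_pow2 <- function(n) 2^ceiling(log2(n))

# FFT bin frequencies in Hz for length n at sampling rate fs (signed,
# standard fft ordering: 0, 1, ..., n/2, -(n/2-1), ..., -1 times fs/n)
fft_freqs <- function(n, fs) {
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)
  if (n %% 2 == 0) k <- c(0:(n / 2), -(n / 2 - 1):-1)
  k * fs / n
}

#' Apply a constant phase shift to a real signal
#'
#' Rotates the positive-frequency Fourier components of `x` by `-phi` radians
#' (and the negative-frequency components by `+phi`, preserving realness).
#' A band-limited signal comes out as the same oscillation lagged by a
#' constant phase at every frequency — the mechanism used to plant a fixed
#' phase lag between coupled channels.
#'
#' @param x numeric vector.
#' @param phi phase lag in radians.
#' @return numeric vector, same length as `x`.
#' @export
phase_shift <- function(x, phi) {
  n <- length(x)
  X <- stats::fft(x)
  f <- fft_freqs(n, 1)
  rot <- exp(-1i * phi * sign(f))
  Re(stats::fft(X * rot, inverse = TRUE)) / n
}

# Band-limited Gaussian noise via zero-phase spectral masking: white noise
# whose Fourier components outside [lo, hi] Hz are zeroed. Exactly band
# limited, numerically stable at the very low normalized frequencies fNIRS
# work lives at (an IIR band-pass there is fragile).
band_noise <- function(n, fs, lo, hi, sd = 1) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- abs(fft_freqs(n, fs))
  X[f < lo | f > hi] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y <- y * (sd / s)
  y
}

# Zero-phase spectral low-pass at `cut` Hz then keep every q-th sample.
# Used to reduce the sampling rate before wavelet analysis of bands far
# below Nyquist; zero-phase so instantaneous phase is untouched in-band.
fft_decimate <- function(x, q, fs) {
  if (q <= 1) return(x)
  n <- length(x)
  X <- stats::fft(x)
  f <- abs(fft_freqs(n, fs))
  X[f > 0.4 * fs / q] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y[seq(1, n, by = q)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
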