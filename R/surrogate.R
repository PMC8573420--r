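#' Amplitude-adjusted Fourier-transform surrogate
#'
#' Classic AAFT: the signal is rank-remapped onto a sorted Gaussian series,
#' the Gaussian series' Fourier phases are randomized (preserving the modulus
#' spectrum and Hermitian symmetry), and the original values are remapped
#' back onto the ranks of the phase-randomized series. The surrogate's sorted
#' values therefore equal the original's sorted values exactly, and its power
#' spectrum matches approximately, while any phase relation with other
#' signals is destroyed — the null model for coherence validity testing.
#'
#' @param x numeric vector, length >= 4.
#' @param seed optional integer; same seed, same surrogate. RNG state of the
#'   caller is preserved.
#' @return numeric vector, a permutation of `x`.
#' @export
aaft_surrogate <- function(x, seed = NULL) {
  n <- length(x)
  if (n < 4) stop("AAFT needs at least 4 samples", call. = FALSE)
  if (diff(range(x)) == 0) {
    warning("constant input: ranks undefined, returning the input")
    return(x)
  }
  run <- function() {
    r <- rank(x, ties.method = "first")
    g <- sort(stats::rnorm(n))[r] # gaussianized copy with x's rank order
    gs <- phase_randomize(g)
    sort(x)[rank(gs, ties.method = "first")]
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Randomize Fourier phases of a real series, preserving the modulus spectrum
# (Hermitian symmetry kept; DC and Nyquist bins, which must stay real, are
# left untouched).
phase_randomize <- function(g) {
  n <- length(g)
  G <- stats::fft(g)
  half <- floor((n - 1) / 2) # bins 2..(half+1) are free; mirror the rest
  if (half > 0) {
    ph <- stats::runif(half, 0, 2 * pi)
    idx <- 2:(half + 1)
    G[idx] <- Mod(G[idx]) * exp(1i * ph)
    G[n + 2 - idx] <- Conj(G[idx])
  }
  Re(stats::fft(G, inverse = TRUE)) / n
}
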