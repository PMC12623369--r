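# Complex Morlet filter bank used by both the PLV and PAC stages.

#' Construct a Morlet wavelet bank
#'
#' Log-spaced center frequencies (the default 43 points span 1.2-200 Hz).
#' The width parameter `m` is the wavelet's cycle count: the Gaussian
#' envelope has temporal SD `sigma_t = m / (2 * pi * f)`, i.e. roughly `m`
#' oscillation cycles under the envelope. Kernels are unit-energy.
#'
#' @param n number of center frequencies (default 43)
#' @param fmin,fmax frequency range in Hz (defaults 1.2 and 200)
#' @param m width (cycle-count) parameter (default 7.5)
#' @param spacing `"log"` (default) or `"linear"`
#' @return object of class `wavelet_bank`: list with `freqs`, `m`, `spacing`
#' @export
make_bank <- function(n = 43, fmin = 1.2, fmax = 200, m = 7.5,
                      spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  stopifnot(fmin < fmax, n >= 2)
  freqs <- if (spacing == "log") {
    exp(seq(log(fmin), log(fmax), length.out = n))
  } else {
    seq(fmin, fmax, length.out = n)
  }
  structure(list(freqs = freqs, m = m, spacing = spacing),
            class = "wavelet_bank")
}

#' Complex Morlet kernel at one frequency
#'
#' @param f center frequency (Hz)
#' @param fs sampling rate (Hz)
#' @param m cycle-count width parameter
#' @param n_sigma Gaussian support half-width in units of `sigma_t`
#' @return complex vector of odd length, unit energy; attribute
#'   `half_support` gives the half-length in samples
#' @export
morlet_kernel <- function(f, fs, m = 7.5, n_sigma = 4) {
  sigma_t <- m / (2 * pi * f)
  hs <- ceiling(n_sigma * sigma_t * fs)
  t <- (-hs:hs) / fs
  k <- exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * f * t)
  k <- k / sqrt(sum(Mod(k)^2))
  attr(k, "half_support") <- hs
  k
}

#' Wavelet coefficients of a multichannel segment at one frequency
#'
#' FFT convolution with the unit-energy Morlet kernel. Samples within half a
#' kernel support of either edge carry boundary bias and are reported via the
#' `valid` index range; downstream metrics exclude them.
#'
#' @param x numeric matrix (time x channel) or vector
#' @param f center frequency (Hz)
#' @param fs sampling rate (Hz)
#' @param m width parameter (default 7.5)
#' @return list: `coef` (complex time x channel matrix), `valid`
#'   (integer vector of unbiased sample indices), `half_support`
#' @export
morlet_transform <- function(x, f, fs, m = 7.5) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- morlet_kernel(f, fs, m)
  hs <- attr(k, "half_support")
  if (n <= 2 * hs) {
    warning(sprintf("segment too short for %g Hz kernel (needs > %d samples)",
                    f, 2 * hs))
    return(NULL)
  }
  L <- length(k)
  N <- stats::nextn(n + L - 1, 2)
  H <- stats::fft(c(k, rep(0, N - L)))
  coef <- matrix(0i, n, ncol(x))
  d <- hs
  for (ch in seq_len(ncol(x))) {
    X <- stats::fft(c(x[, ch], rep(0, N - n)))
    y <- stats::fft(X * H, inverse = TRUE) / N
    coef[, ch] <- y[(d + 1):(d + n)]
  }
  colnames(coef) <- colnames(x)
  list(coef = coef, valid = (hs + 1):(n - hs), half_support = hs)
}
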