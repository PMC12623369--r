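# Internal numerical helpers shared across modules.

#' Periodic Hann window
#' @param n window length in samples
#' @return numeric vector of length `n`
#' @keywords internal
#' @noRd
hann_periodic <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))
}

# Symmetric Hann window (used for smoothing kernels).
hann_symmetric <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

# Linear convolution of a real signal with a (possibly complex) kernel via FFT,
# returning the "same"-length central part with the (L-1)/2 group delay of a
# symmetric kernel compensated. Kernel length must be odd.
conv_same <- function(x, h) {
  n <- length(x)
  L <- length(h)
  stopifnot(L %% 2 == 1)
  N <- stats::nextn(n + L - 1, 2)
  X <- stats::fft(c(x, rep(0, N - n)))
  H <- stats::fft(c(h, rep(0, N - L)))
  y <- stats::fft(X * H, inverse = TRUE) / N
  d <- (L - 1) / 2
  y[(d + 1):(d + n)]
}

# As conv_same but reuses a precomputed zero-padded FFT of x (length N).
conv_same_fft <- function(X, N, n, h) {
  L <- length(h)
  H <- stats::fft(c(h, rep(0, N - L)))
  y <- stats::fft(X * H, inverse = TRUE) / N
  d <- (L - 1) / 2
  y[(d + 1):(d + n)]
}

# Full linear convolution of two real vectors via power-of-2 padded FFT.
conv_full <- function(a, b) {
  n <- length(a) + length(b) - 1
  N <- stats::nextn(n, 2)
  y <- stats::fft(stats::fft(c(a, rep(0, N - length(a)))) *
                    stats::fft(c(b, rep(0, N - length(b)))), inverse = TRUE)
  Re(y[1:n]) / N
}

# Evaluate a local computation under a fixed RNG seed without disturbing the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Run lengths of a logical vector as (start, end) index pairs.
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
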