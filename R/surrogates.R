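# Circular-split surrogates: destroy cross-channel coupling while preserving
# each channel's own temporal structure (sample multiset and magnitude
# spectrum are exactly preserved by rotation).

#' Circular-split surrogate of a time series
#'
#' Splits the series at sample `k` and swaps the two halves:
#' `x_surr = c(x[(k+1):n], x[1:k])`. The partner signal of a pair is left
#' untouched, so any cross-channel phase relation is scrambled while the
#' rotated channel's autocorrelation is intact (up to the single seam).
#'
#' @param x numeric or complex vector
#' @param k split point, `0 < k < length(x)`
#' @return the rotated series
#' @export
split_surrogate <- function(x, k) {
  n <- length(x)
  if (!(k > 0 && k < n)) stop("split point k must satisfy 0 < k < length(x)")
  c(x[(k + 1):n], x[1:k])
}

#' Surrogate ensemble of a bivariate coupling metric
#'
#' Draws `n_surrogates` seeded split points (kept at least `min_shift`
#' samples away from either end so a surrogate is never a near-identity
#' rotation), rotates `x`, and evaluates `metric_fn(x_rot, y)` per draw.
#' Rotation is intended to run on narrow-band (wavelet-filtered) series, the
#' stage at which coupling metrics operate.
#'
#' @param x,y equal-length series (typically complex wavelet coefficients)
#' @param metric_fn function of `(x, y)` returning a scalar metric
#' @param n_surrogates ensemble size (default 50)
#' @param seed RNG seed
#' @param min_shift minimum rotation distance in samples (e.g. one kernel
#'   support); capped at a quarter of the series length
#' @return list: `values` (length `n_surrogates`), `mean`, `k` (split points)
#' @export
surrogate_ensemble <- function(x, y, metric_fn, n_surrogates = 50, seed = 1,
                               min_shift = 1) {
  n <- length(x)
  stopifnot(length(y) == n, n_surrogates >= 1)
  lo <- min(max(1, min_shift), floor(n / 4))
  hi <- n - lo
  ks <- with_seed(seed, sample(lo:hi, n_surrogates, replace = TRUE))
  vals <- vapply(ks, function(k) metric_fn(split_surrogate(x, k), y), 0)
  list(values = vals, mean = mean(vals), k = ks)
}
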