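# Phase-locking value: complex PLV between narrow-band signals, pairwise
# matrices, and region-level aggregate spectra with a surrogate reference.

#' Complex phase-locking value
#'
#' `cPLV = (1/K) * sum_k x'(k) * Conj(y'(k)) / (|x'(k)| * |y'(k)|)` over the
#' K valid samples; `PLV = |cPLV|` lies in [0, 1] (1 = perfect phase locking).
#' Samples where either coefficient has zero magnitude are excluded from K.
#'
#' @param x,y complex wavelet-coefficient vectors of equal length
#' @return the complex PLV; take `Mod()` for the PLV
#' @export
cplv <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- Mod(x) > 0 & Mod(y) > 0
  if (!all(keep)) {
    message(sum(!keep), " zero-magnitude sample(s) excluded from K")
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) == 0) stop("no valid samples (K = 0)")
  mean(x * Conj(y) / (Mod(x) * Mod(y)))
}

# Channel x channel PLV matrix from a complex coefficient matrix
# (time x channel), rows restricted to the valid range beforehand.
plv_matrix <- function(coef) {
  Z <- coef / Mod(coef)
  K <- nrow(Z)
  P <- Mod(Conj(t(Z)) %*% Z) / K
  diag(P) <- 1
  dimnames(P) <- list(colnames(coef), colnames(coef))
  P
}

# Mean over unordered channel pairs of a PLV matrix restricted to the given
# channel sets (within-region when a == b, between-region otherwise).
pair_mean <- function(P, a, b) {
  if (identical(a, b)) {
    if (length(a) < 2) return(NA_real_)
    sub <- P[a, a, drop = FALSE]
    mean(sub[upper.tri(sub)])
  } else {
    if (length(a) < 1 || length(b) < 1) return(NA_real_)
    mean(P[a, b, drop = FALSE])
  }
}

#' PLV connectivity spectra within and between regions
#'
#' For every segment and every bank frequency, computes the channel-pair PLV
#' matrix from Morlet coefficients (edge samples trimmed), averages over
#' unordered pairs within S1, within RFA and across the two regions, and
#' finally averages over segments. A surrogate reference spectrum is computed
#' by independently circular-rotating every channel's coefficient series
#' (coupling-destroying, autocorrelation-preserving) and re-evaluating the
#' mean off-diagonal PLV.
#'
#' @param rec an [lfp_recording()] (bipolar LFP at 1 kHz)
#' @param segments a `segment_set` from [extract_sws_segments()]
#' @param bank a `wavelet_bank` from [make_bank()]
#' @param n_surrogates surrogate draws for the reference spectrum
#'   (default 100; 0 disables)
#' @param seed RNG seed for the surrogate rotations
#' @return list of class `plv_result`: `freqs`, `matrices` (channel x
#'   channel x frequency, segment-averaged), `aggregates` (data.frame
#'   `freq_hz`, `pair_type`, `plv`), `surrogate` (data.frame `freq_hz`,
#'   `plv`), `channels`, `region_of`
#' @export
plv_pipeline <- function(rec, segments, bank = make_bank(),
                         n_surrogates = 100, seed = 1) {
  chs <- segments$channels
  if (length(chs) < 2) stop("need at least 2 good channels")
  wins <- segments$windows
  if (nrow(wins) == 0) stop("empty segment set")
  region <- rec$region[chs]
  s1 <- chs[region == "S1"]
  rfa <- chs[region == "RFA"]
  nf <- length(bank$freqs)
  mats <- array(0, c(length(chs), length(chs), nf),
                dimnames = list(chs, chs, NULL))
  nseg_used <- numeric(nf)
  agg <- array(NA_real_, c(nf, 3, nrow(wins)))
  surr <- matrix(NA_real_, nf, nrow(wins))
  with_seed(seed, for (s in seq_len(nrow(wins))) {
    xs <- rec$data[segment_indices(rec, wins$start_s[s], wins$end_s[s]), chs,
                   drop = FALSE]
    for (i in seq_len(nf)) {
      wt <- morlet_transform(xs, bank$freqs[i], rec$rate, bank$m)
      if (is.null(wt)) next
      Z <- wt$coef[wt$valid, , drop = FALSE]
      P <- plv_matrix(Z)
      mats[, , i] <- mats[, , i] + P
      nseg_used[i] <- nseg_used[i] + 1
      agg[i, 1, s] <- pair_mean(P, s1, s1)
      agg[i, 2, s] <- pair_mean(P, rfa, rfa)
      agg[i, 3, s] <- pair_mean(P, s1, rfa)
      if (n_surrogates > 0) {
        K <- nrow(Z)
        lo <- min(wt$half_support, floor(K / 4))
        sv <- numeric(n_surrogates)
        U <- Z / Mod(Z)
        for (r in seq_len(n_surrogates)) {
          Zs <- U
          ks <- sample(lo:(K - lo), ncol(U), replace = TRUE)
          for (ch in seq_len(ncol(U))) {
            Zs[, ch] <- split_surrogate(U[, ch], ks[ch])
          }
          Ps <- Mod(Conj(t(Zs)) %*% Zs) / K
          sv[r] <- mean(Ps[upper.tri(Ps)])
        }
        surr[i, s] <- mean(sv)
      }
    }
  })
  for (i in seq_len(nf)) {
    if (nseg_used[i] > 0) mats[, , i] <- mats[, , i] / nseg_used[i]
    else mats[, , i] <- NA_real_
  }
  pair_types <- c("S1S1", "RFARFA", "S1RFA")
  aggregates <- do.call(rbind, lapply(1:3, function(j) {
    data.frame(freq_hz = bank$freqs, pair_type = pair_types[j],
               plv = rowMeans(agg[, j, , drop = FALSE], na.rm = TRUE),
               row.names = NULL)
  }))
  aggregates$plv[is.nan(aggregates$plv)] <- NA_real_
  structure(list(freqs = bank$freqs, matrices = mats,
                 aggregates = aggregates,
                 surrogate = data.frame(freq_hz = bank$freqs,
                                        plv = rowMeans(surr, na.rm = TRUE)),
                 channels = chs, region_of = region),
            class = "plv_result")
}
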