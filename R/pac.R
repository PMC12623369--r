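# Phase-amplitude coupling on the fixed low-frequency x ratio grid, with
# circular-split surrogate normalization and intra-/inter-areal direction.

PAC_LF_HZ <- c(1.2, 2.4, 3.7, 5.9, 8.6, 13.2, 19.5, 29.5, 47.3, 68.1)
PAC_RATIOS <- c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 14.06, 17.96, 22.96, 29.34,
                37.49, 47.91, 61.23, 78.25, 100, 110, 149.11, 202.13)

#' The PAC low-frequency x ratio grid
#'
#' High frequencies are generated multiplicatively (`hf = lf * ratio`); cells
#' whose HF exceeds `hf_max` (200 Hz) are invalid and never evaluated.
#'
#' @param lf_hz low-frequency values in Hz
#' @param ratios HF/LF multipliers
#' @param hf_max maximum admissible high frequency in Hz (default 200)
#' @return data.frame (`lf_hz`, `ratio`, `hf_hz`, `valid`)
#' @export
pac_grid <- function(lf_hz = PAC_LF_HZ, ratios = PAC_RATIOS, hf_max = 200) {
  g <- expand.grid(ratio = ratios, lf_hz = lf_hz)[, c("lf_hz", "ratio")]
  g$hf_hz <- g$lf_hz * g$ratio
  g$valid <- g$hf_hz <= hf_max
  rownames(g) <- NULL
  g
}

# Phase/envelope phasor series for one (lf, hf) cell: the unit phasor of x's
# lf-band phase, and the unit phasor of the lf-filtered amplitude envelope of
# y's hf band, both restricted to the jointly valid samples.
pac_phasors <- function(x, y, lf_hz, hf_hz, fs, m = 7.5) {
  wx <- morlet_transform(x, lf_hz, fs, m)
  wy <- morlet_transform(y, hf_hz, fs, m)
  if (is.null(wx) || is.null(wy)) stop("segment too short for the lf kernel")
  A <- Mod(wy$coef[, 1])
  we <- morlet_transform(A, lf_hz, fs, m)
  trim <- wx$half_support + wy$half_support
  n <- length(x)
  if (n <= 2 * trim) stop("segment too short for the lf kernel")
  valid <- (trim + 1):(n - trim)
  zx <- wx$coef[valid, 1]
  ze <- we$coef[valid, 1]
  list(zx = zx / Mod(zx), ze = ze / Mod(ze), valid = valid,
       min_shift = 2 * wx$half_support + 1)
}

#' Raw phase-amplitude coupling between two signals
#'
#' The phase of `x`'s low-frequency component is compared with the phase of
#' the low-frequency-filtered amplitude envelope of `y`'s high-frequency
#' component: `PAC = |(1/K) * sum exp(i * (theta_x_lf - theta_env))|`.
#' The envelope enters through its lf-band phase (the envelope is filtered
#' at the same frequency as the LF), which is what makes the phase
#' difference well defined. All filtering uses the Morlet machinery with
#' kernels centered at the exact `lf_hz` and `hf_hz` values.
#'
#' @param x phase-providing signal (numeric vector)
#' @param y amplitude-providing signal (same length)
#' @param lf_hz low frequency (Hz)
#' @param hf_hz high frequency (Hz); must not exceed 200
#' @param fs sampling rate (Hz)
#' @param m Morlet width parameter (default 7.5)
#' @param n_surrogates if > 0, also return circular-split surrogate PAC
#'   values (rotating the lf phase series) and the normalized nPAC
#' @param seed RNG seed for surrogate split points
#' @return list: `raw` in [0, 1]; with surrogates also `surrogates`, `npac`
#' @export
pac_value <- function(x, y, lf_hz, hf_hz, fs, m = 7.5, n_surrogates = 0,
                      seed = 1) {
  if (hf_hz > 200) {
    stop("invalid PAC cell: hf = ", hf_hz, " Hz exceeds 200 Hz")
  }
  ph <- pac_phasors(x, y, lf_hz, hf_hz, fs, m)
  raw <- Mod(mean(ph$zx * Conj(ph$ze)))
  out <- list(raw = raw)
  if (n_surrogates > 0) {
    ens <- surrogate_ensemble(ph$zx, ph$ze,
                              function(a, b) Mod(mean(a * Conj(b))),
                              n_surrogates = n_surrogates, seed = seed,
                              min_shift = ph$min_shift)
    out$surrogates <- ens$values
    out$npac <- normalize_pac(raw, ens$values)
  }
  out
}

#' Normalize a raw PAC value by its surrogate ensemble
#'
#' `nPAC = raw / mean(surrogates)`; values near 1 indicate coupling at the
#' chance level, values above 1 coupling beyond the null.
#'
#' @param raw observed raw PAC
#' @param surrogate_raws surrogate raw PAC values (>= 1)
#' @return the normalized PAC
#' @export
normalize_pac <- function(raw, surrogate_raws) {
  if (length(surrogate_raws) < 1) stop("need at least one surrogate value")
  m <- mean(surrogate_raws)
  if (m == 0) stop("degenerate input: surrogate mean is zero")
  raw / m
}

#' Surrogate-normalized comodulogram over segments and channel pairs
#'
#' Evaluates nPAC on every valid grid cell for the directed channel pairs of
#' the requested direction (`"S1S1"`/`"RFARFA"` intra-areal: ordered pairs of
#' distinct channels within the region; `"S1RFA"`/`"RFAS1"` inter-areal:
#' phase channel in the first region, amplitude channel in the second),
#' averages over pairs and segments, and projects the lf x ratio grid into
#' lf x hf space. The HF-mean spectrum averages nPAC over all LF rows
#' contributing to each logarithmic HF bin.
#'
#' @param rec an [lfp_recording()]
#' @param segments a `segment_set`
#' @param direction one of `"S1S1"`, `"RFARFA"`, `"S1RFA"`, `"RFAS1"`
#' @param grid a [pac_grid()] (possibly restricted for speed)
#' @param n_surrogates surrogate draws per cell (default 50)
#' @param seed RNG seed
#' @param m Morlet width parameter
#' @param max_pairs cap on directed channel pairs (sampled deterministically
#'   from the seed when exceeded); keeps large montages tractable
#' @param hf_bins number of logarithmic HF bins for the HF-mean spectrum
#' @return list of class `pac_result`: `cells` (data.frame `lf_hz`, `ratio`,
#'   `hf_hz`, `raw_pac`, `npac`), `hf_spectrum` (data.frame `hf_hz`, `npac`),
#'   `direction`, `n_pairs`
#' @export
comodulogram <- function(rec, segments, direction = "S1RFA",
                         grid = pac_grid(), n_surrogates = 50, seed = 1,
                         m = 7.5, max_pairs = 4, hf_bins = 24) {
  chs <- segments$channels
  region <- rec$region[chs]
  parse <- switch(direction,
                  S1S1 = c("S1", "S1"), RFARFA = c("RFA", "RFA"),
                  S1RFA = c("S1", "RFA"), RFAS1 = c("RFA", "S1"),
                  stop("unknown direction: ", direction))
  pa <- chs[region == parse[1]]
  pb <- chs[region == parse[2]]
  pairs <- expand.grid(phase = pa, amp = pb, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$phase != pairs$amp, , drop = FALSE]
  if (nrow(pairs) == 0) {
    warning("no channel pair for direction ", direction)
    return(NULL)
  }
  if (nrow(pairs) > max_pairs) {
    keep <- with_seed(seed, sample.int(nrow(pairs), max_pairs))
    pairs <- pairs[keep, , drop = FALSE]
  }
  g <- grid[grid$valid, , drop = FALSE]
  wins <- segments$windows
  acc_raw <- acc_npac <- matrix(0, nrow(g), 1)
  n_acc <- 0
  for (s in seq_len(nrow(wins))) {
    idx <- segment_indices(rec, wins$start_s[s], wins$end_s[s])
    for (p in seq_len(nrow(pairs))) {
      x <- rec$data[idx, pairs$phase[p]]
      y <- rec$data[idx, pairs$amp[p]]
      v <- pac_cells(x, y, g, rec$rate, m, n_surrogates,
                     seed + 1000 * s + p)
      acc_raw <- acc_raw + v$raw
      acc_npac <- acc_npac + v$npac
      n_acc <- n_acc + 1
    }
  }
  cells <- data.frame(lf_hz = g$lf_hz, ratio = g$ratio, hf_hz = g$hf_hz,
                      raw_pac = acc_raw[, 1] / n_acc,
                      npac = acc_npac[, 1] / n_acc)
  edges <- exp(seq(log(2), log(200), length.out = hf_bins + 1))
  bin <- findInterval(cells$hf_hz, edges, rightmost.closed = TRUE)
  bin[bin < 1] <- 1
  centers <- sqrt(edges[-1] * edges[-length(edges)])
  hf_spec <- stats::aggregate(cells$npac, list(bin = bin), mean)
  hf_spectrum <- data.frame(hf_hz = centers[hf_spec$bin], npac = hf_spec$x)
  structure(list(cells = cells, hf_spectrum = hf_spectrum,
                 direction = direction, n_pairs = nrow(pairs)),
            class = "pac_result")
}

# nPAC for every valid cell of a grid, averaged over the directed channel
# pairs (phase column of `x`, amplitude column of `y`).
#
# The heavy work is shared: the forward FFT of every channel is computed
# once, the lf phase series once per distinct (lf, phase channel), the hf
# envelope chain once per distinct (lf, hf, amplitude channel). A circular
# rotation of the phase series by k samples makes the raw PAC a lag-k
# circular cross-correlation of the two phasor series, so the whole rotation
# family comes from one extra FFT triple per pair and cell; the seeded
# surrogate ensemble draws its split points from that family.
pac_cells <- function(x, y, g, fs, m = 7.5, n_surrogates = 50, seed = 1) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  stopifnot(nrow(y) == n)
  lf_list <- sort(unique(g$lf_hz))
  Lmax <- 2 * attr(morlet_kernel(min(lf_list), fs, m), "half_support") + 1
  N <- stats::nextn(n + Lmax - 1, 2)
  FX <- lapply(seq_len(ncol(x)), function(j)
    stats::fft(c(x[, j], rep(0, N - n))))
  FY <- lapply(seq_len(ncol(y)), function(j)
    stats::fft(c(y[, j], rep(0, N - n))))
  kern <- lapply(lf_list, function(f) morlet_kernel(f, fs, m))
  names(kern) <- as.character(lf_list)
  kfft <- lapply(kern, function(k) stats::fft(c(k, rep(0, N - length(k)))))
  hs_lf <- vapply(kern, function(k) attr(k, "half_support"), 0)
  zx_lf <- list()   # phase phasors per (lf, phase channel)
  for (lf in names(kern)) {
    zx_lf[[lf]] <- lapply(FX, function(Xj) {
      co <- conv_same_fft(Xj, N, n, kern[[lf]])
      co / Mod(co)
    })
  }
  raw <- npac <- rep(NA_real_, nrow(g))
  env_cache <- new.env()
  for (i in seq_len(nrow(g))) {
    lf <- as.character(g$lf_hz[i]); hf <- g$hf_hz[i]
    key <- sprintf("%.6f_%s", hf, lf)
    if (!exists(key, envir = env_cache)) {
      khf <- morlet_kernel(hf, fs, m)
      LA <- length(kern[[lf]])
      d <- (LA - 1) / 2
      zes <- lapply(FY, function(Yj) {
        A <- Mod(conv_same_fft(Yj, N, n, khf))
        FA <- stats::fft(c(A, rep(0, N - n)))
        ze <- stats::fft(FA * kfft[[lf]], inverse = TRUE)[(d + 1):(d + n)] / N
        ze / Mod(ze)
      })
      assign(key, list(zes = zes, hs_y = attr(khf, "half_support")),
             envir = env_cache)
    }
    ec <- get(key, envir = env_cache)
    trim <- hs_lf[[lf]] + ec$hs_y
    if (n <= 2 * trim) next
    K <- good_fft_len(n - 2 * trim)   # smooth FFT length for the lag family
    valid <- (trim + 1):(trim + K)
    lo <- min(max(1, 2 * hs_lf[[lf]] + 1), floor(K / 4))
    raws <- npacs <- numeric(0)
    for (jx in seq_along(FX)) {
      zx <- zx_lf[[lf]][[jx]][valid]
      for (jy in seq_along(FY)) {
        ze <- ec$zes[[jy]][valid]
        # circular cross-correlation over the valid window: lag 0 is the
        # observed PAC, lag k the split-surrogate PAC
        cc <- circ_xcorr(zx, ze, K)
        ks <- with_seed(seed + i + 37L * jx + 101L * jy,
                        sample(lo:(K - lo), n_surrogates, replace = TRUE))
        raws <- c(raws, cc[1])
        npacs <- c(npacs, normalize_pac(cc[1], cc[ks + 1]))
      }
    }
    raw[i] <- mean(raws)
    npac[i] <- mean(npacs)
  }
  list(raw = raw, npac = npac)
}

# Modulus of the circular cross-correlation (1/K) sum_t a(t+k) Conj(b(t))
# for all lags k = 0..K-1.
circ_xcorr <- function(a, b, K) {
  Mod(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE)) / K^2
}

# Largest length <= n whose prime factors are all <= 13 (keeps the
# mixed-radix FFT fast); never loses more than ~2% of the window.
good_fft_len <- function(n) {
  for (k in n:max(2, floor(0.97 * n))) {
    m <- k
    for (p in c(2, 3, 5, 7, 11, 13)) while (m %% p == 0) m <- m / p
    if (m == 1) return(k)
  }
  n
}
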