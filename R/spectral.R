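# Welch power spectral density and region/group aggregation.

#' Welch power spectral density
#'
#' Hann-windowed averaged periodogram with 50% overlap and density scaling
#' (power per Hz); frequency resolution is `fs / nperseg` (about 0.24 Hz for
#' the 1 kHz / 4096-sample default). Blocks are constant-detrended.
#'
#' @param x numeric vector of samples
#' @param fs_hz sampling rate (Hz)
#' @param nperseg samples per Welch block (default 4096)
#' @param overlap fractional block overlap (default 0.5)
#' @param detrend `"constant"` (subtract block mean) or `"none"`
#' @return list of class `psd`: `freq` (Hz) and `power` (uV^2/Hz), one-sided
#' @export
welch_psd <- function(x, fs_hz = 1000, nperseg = 4096, overlap = 0.5,
                      detrend = c("constant", "none")) {
  detrend <- match.arg(detrend)
  n <- length(x)
  if (n < nperseg) {
    stop("segment too short for Welch block: need at least ", nperseg,
         " samples, got ", n)
  }
  step <- max(1, round(nperseg * (1 - overlap)))
  starts <- seq(1, n - nperseg + 1, by = step)
  w <- hann_periodic(nperseg)
  scale <- 1 / (fs_hz * sum(w^2))
  segs <- vapply(starts, function(s) x[s:(s + nperseg - 1)], numeric(nperseg))
  if (detrend == "constant") {
    segs <- sweep(segs, 2, colMeans(segs))
  }
  segs <- segs * w
  P <- Mod(stats::mvfft(segs))^2 * scale
  nf <- floor(nperseg / 2) + 1
  pxx <- rowMeans(P)[1:nf]
  # one-sided: double everything except DC and (for even nperseg) Nyquist
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nperseg %% 2 == 0) dbl[nf] <- 1
  structure(list(freq = (0:(nf - 1)) * fs_hz / nperseg, power = pxx * dbl),
            class = "psd")
}

#' Per-channel Welch PSD over a set of segments
#'
#' @param rec an [lfp_recording()]
#' @param segments a `segment_set` from [extract_sws_segments()]
#' @param ... passed to [welch_psd()]
#' @return list: `freq`, `power` array (freq x channel x segment)
#' @export
segment_psd <- function(rec, segments, ...) {
  chs <- segments$channels
  wins <- segments$windows
  if (nrow(wins) == 0) stop("empty segment set")
  first <- welch_psd(rec$data[segment_indices(rec, wins$start_s[1],
                                              wins$end_s[1]), chs[1]],
                     fs_hz = rec$rate, ...)
  pow <- array(NA_real_, c(length(first$freq), length(chs), nrow(wins)),
               dimnames = list(NULL, chs, NULL))
  for (s in seq_len(nrow(wins))) {
    idx <- segment_indices(rec, wins$start_s[s], wins$end_s[s])
    for (ch in chs) {
      pow[, ch, s] <- welch_psd(rec$data[idx, ch], fs_hz = rec$rate, ...)$power
    }
  }
  list(freq = first$freq, power = pow)
}

#' Average PSDs across channels within each region
#'
#' Arithmetic mean over good channels within region, then over segments.
#'
#' @param psd output of [segment_psd()]
#' @param region_of named character vector channel -> region
#' @return list: `freq`, `region` (freq x region matrix of mean power)
#' @export
region_average <- function(psd, region_of) {
  chs <- dimnames(psd$power)[[2]]
  regions <- unique(unname(region_of[chs]))
  out <- sapply(regions, function(r) {
    sel <- chs[region_of[chs] == r]
    if (length(sel) == 0) {
      warning("region ", r, " has no good channel; omitted")
      return(rep(NA_real_, length(psd$freq)))
    }
    rowMeans(psd$power[, sel, , drop = FALSE], dims = 1)
  })
  list(freq = psd$freq, region = out)
}

#' Bootstrap confidence band over animals
#'
#' Percentile bootstrap (resampling animals with replacement) of the group
#' mean spectrum; 97% interval by default, matching the group-figure
#' convention for inter-subject spread.
#'
#' @param mat animal x frequency matrix of spectra
#' @param n_boot bootstrap draws (default 1000)
#' @param conf confidence level (default 0.97)
#' @param seed RNG seed
#' @return list: `mean`, `lo`, `hi` (vectors over frequency)
#' @export
group_bootstrap_ci <- function(mat, n_boot = 1000, conf = 0.97, seed = 1) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  boot <- with_seed(seed, {
    replicate(n_boot, colMeans(mat[sample.int(n, n, replace = TRUE), ,
                                   drop = FALSE]))
  })
  a <- (1 - conf) / 2
  list(mean = colMeans(mat),
       lo = apply(boot, 1, stats::quantile, probs = a),
       hi = apply(boot, 1, stats::quantile, probs = 1 - a))
}
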