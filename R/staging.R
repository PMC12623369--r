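# Sleep-wake staging from spectral-ratio state maps, and selection of
# artifact-free slow-wave-sleep analysis segments.

#' Per-epoch spectral power ratios
#'
#' Computes, for every channel and every `win_s`-second window advanced by
#' `step_s` seconds, two band-power ratios from a Hann-tapered periodogram:
#' ratio 1 = power(0.5-20 Hz) / power(0.5-55 Hz) and
#' ratio 2 = power(0.5-4.5 Hz) / power(0.5-9 Hz). Ratio 2 tracks delta
#' dominance (slow-wave sleep), ratio 1 separates theta-rich sleep from
#' desynchronized wakefulness.
#'
#' @param rec an [lfp_recording()] at 1000 Hz
#' @param win_s window length in seconds (default 2)
#' @param step_s window step in seconds (default 1)
#' @return list with `epoch_time` (window centers, s), `ratio1` and `ratio2`
#'   (epoch x channel matrices; `NA` for all-zero windows)
#' @export
spectral_ratios <- function(rec, win_s = 2, step_s = 1) {
  fs <- rec$rate
  nwin <- round(win_s * fs)
  nstep <- round(step_s * fs)
  n <- nrow(rec$data)
  if (n < nwin) stop("recording shorter than one window")
  starts <- seq(1, n - nwin + 1, by = nstep)
  nep <- length(starts)
  w <- hann_periodic(nwin)
  f <- (0:(nwin - 1)) * fs / nwin
  half <- 1:(floor(nwin / 2))      # positive frequencies, DC excluded
  fh <- f[half + 1]
  in_band <- function(lo, hi) fh >= lo & fh <= hi
  b_num1 <- in_band(0.5, 20);  b_den1 <- in_band(0.5, 55)
  b_num2 <- in_band(0.5, 4.5); b_den2 <- in_band(0.5, 9)
  ratio1 <- matrix(NA_real_, nep, ncol(rec$data))
  ratio2 <- matrix(NA_real_, nep, ncol(rec$data))
  for (ch in seq_len(ncol(rec$data))) {
    segs <- vapply(starts, function(s) rec$data[s:(s + nwin - 1), ch],
                   numeric(nwin))
    segs <- segs * w
    P <- Mod(stats::mvfft(segs))^2
    P <- P[half + 1, , drop = FALSE]
    zero <- colSums(P) == 0
    den1 <- colSums(P[b_den1, , drop = FALSE])
    den2 <- colSums(P[b_den2, , drop = FALSE])
    r1 <- colSums(P[b_num1, , drop = FALSE]) / den1
    r2 <- colSums(P[b_num2, , drop = FALSE]) / den2
    r1[zero | den1 == 0] <- NA
    r2[zero | den2 == 0] <- NA
    ratio1[, ch] <- r1
    ratio2[, ch] <- r2
  }
  colnames(ratio1) <- colnames(ratio2) <- rec$channels
  list(epoch_time = (starts - 1) / fs + win_s / 2,
       ratio1 = ratio1, ratio2 = ratio2)
}

# First principal component across channels, oriented to correlate positively
# with the cross-channel mean of the input matrix.
pc1_oriented <- function(mat) {
  if (ncol(mat) < 2) {
    warning("fewer than 2 channels: using channel mean instead of PC1")
    return(rowMeans(mat))
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  s <- pc$x[, 1]
  m <- rowMeans(mat)
  if (stats::sd(s) > 0 && stats::cor(s, m) < 0) s <- -s
  s
}

# Circular convolution with a unit-sum kernel: exactly mean-preserving.
smooth_circular <- function(x, kernel) {
  kernel <- kernel / sum(kernel)
  n <- length(x)
  k <- length(kernel)
  if (k >= n) return(rep(mean(x), n))
  kpad <- rep(0, n)
  half <- (k - 1) / 2
  idx <- ((seq_len(k) - 1 - half) %% n) + 1
  kpad[idx] <- kernel
  Re(stats::fft(stats::fft(x) * stats::fft(kpad), inverse = TRUE)) / n
}

#' Build the 2-D sleep state map
#'
#' For each spectral ratio, extracts the first principal component across
#' channels over epochs (orientation fixed so the PC correlates positively
#' with the cross-channel mean ratio) and smooths it with a unit-sum 20-s
#' Hann kernel (applied circularly so the kernel mass, and hence the series
#' mean, is preserved exactly). The map plots ratio-2 PC on x and ratio-1 PC
#' on y; vigilance states form clusters in this plane.
#'
#' @param ratios output of [spectral_ratios()]
#' @param smooth_s smoothing kernel length in seconds (default 20)
#' @return list of class `state_map` with `epoch_time`, `x`, `y`
#'   (`NA` where a ratio was undefined)
#' @export
build_state_map <- function(ratios, smooth_s = 20) {
  ok <- stats::complete.cases(ratios$ratio1) &
    stats::complete.cases(ratios$ratio2)
  if (sum(ok) < smooth_s) stop("need at least ", smooth_s, " scored epochs")
  step <- if (length(ratios$epoch_time) > 1) {
    diff(ratios$epoch_time[1:2])
  } else 1
  klen <- 2 * floor(smooth_s / step / 2) + 1
  kernel <- hann_symmetric(klen)
  x <- y <- rep(NA_real_, length(ratios$epoch_time))
  x[ok] <- smooth_circular(pc1_oriented(ratios$ratio2[ok, , drop = FALSE]),
                           kernel)
  y[ok] <- smooth_circular(pc1_oriented(ratios$ratio1[ok, , drop = FALSE]),
                           kernel)
  structure(list(epoch_time = ratios$epoch_time, x = x, y = y),
            class = "state_map")
}

#' Cluster the state map into WK / SWS / REM
#'
#' k-means (k = 3, multiple restarts, fixed seed) on the (x, y) map points.
#' Clusters are assigned positionally: SWS is the cluster with the highest
#' mean x (delta-dominant); of the remaining two, REM has the higher mean y
#' (theta-rich sleep) and WK is the last. A degenerate map (near-zero
#' variance, or clusters that do not separate beyond `min_separation` times
#' the within-cluster spread) yields all-UNSCORED.
#'
#' @param map a `state_map` from [build_state_map()]
#' @param k number of clusters (default 3)
#' @param seed RNG seed for the k-means restarts
#' @param nstart k-means restarts (default 20)
#' @param min_separation minimum ratio of inter-center distance to mean
#'   within-cluster SD for the clustering to count as real structure
#' @return list of class `hypnogram` with `epoch_time` and `label`
#'   (factor with levels WK, SWS, REM, UNSCORED)
#' @export
cluster_states <- function(map, k = 3, seed = 1, nstart = 20,
                           min_separation = 2) {
  labels <- rep("UNSCORED", length(map$epoch_time))
  ok <- is.finite(map$x) & is.finite(map$y)
  pts <- cbind(map$x[ok], map$y[ok])
  degenerate <- sum(ok) < k ||
    (stats::sd(pts[, 1]) < 1e-12 && stats::sd(pts[, 2]) < 1e-12)
  if (!degenerate) {
    km <- with_seed(seed, stats::kmeans(pts, centers = k, nstart = nstart,
                                        iter.max = 100))
    within_sd <- sqrt(mean(km$withinss / pmax(km$size - 1, 1)))
    dmin <- min(stats::dist(km$centers))
    if (within_sd == 0 || dmin / within_sd >= min_separation) {
      cl <- km$cluster
      sws <- which.max(km$centers[, 1])
      rest <- setdiff(seq_len(k), sws)
      rem <- rest[which.max(km$centers[rest, 2])]
      wk <- setdiff(rest, rem)
      lab <- character(k)
      lab[sws] <- "SWS"; lab[rem] <- "REM"; lab[wk] <- "WK"
      labels[ok] <- lab[cl]
    }
  }
  structure(list(epoch_time = map$epoch_time,
                 label = factor(labels,
                                levels = c("WK", "SWS", "REM", "UNSCORED"))),
            class = "hypnogram")
}

#' Extract artifact-free SWS analysis segments
#'
#' Maximal runs of consecutive SWS epochs are tiled into non-overlapping
#' `dur_s`-second windows. A window is dropped when any good channel shows an
#' amplitude excursion beyond `artifact_z` robust standard deviations
#' (1.4826 x MAD) from its median. Channels flagged by
#' [flag_bad_channels()] are excluded from the artifact screen and from the
#' returned channel list.
#'
#' @param hyp a `hypnogram` aligned to `rec`
#' @param rec the [lfp_recording()] the hypnogram was scored on
#' @param quality optional data.frame from [flag_bad_channels()]
#' @param dur_s segment duration in seconds (default 120)
#' @param artifact_z robust-SD threshold for amplitude excursions (default 8)
#' @return list of class `segment_set`: `windows` data.frame
#'   (`start_s`, `end_s`), `channels` (good channels)
#' @export
extract_sws_segments <- function(hyp, rec, quality = NULL, dur_s = 120,
                                 artifact_z = 8) {
  good <- if (is.null(quality)) rec$channels else {
    quality$channel[quality$flag == "good"]
  }
  good <- intersect(rec$channels, good)
  is_sws <- hyp$label == "SWS"
  runs <- logical_runs(as.vector(is_sws))
  dur_rec <- rec_duration(rec)
  # epoch i covers [center - 0.5, center + 0.5); runs extend half an epoch
  # window (1 s) beyond the first/last center, clipped to the recording.
  wins <- list()
  if (nrow(runs) > 0) {
    for (i in seq_len(nrow(runs))) {
      t0 <- max(0, hyp$epoch_time[runs$start[i]] - 1)
      t1 <- min(dur_rec, hyp$epoch_time[runs$end[i]] + 1)
      nwin <- floor((t1 - t0) / dur_s)
      if (nwin > 0) {
        s <- t0 + dur_s * (0:(nwin - 1))
        wins[[length(wins) + 1]] <- data.frame(start_s = s, end_s = s + dur_s)
      }
    }
  }
  wins <- if (length(wins)) do.call(rbind, wins) else {
    data.frame(start_s = numeric(0), end_s = numeric(0))
  }
  if (nrow(wins) > 0 && length(good) > 0) {
    med <- apply(rec$data[, good, drop = FALSE], 2, stats::median)
    rsd <- apply(rec$data[, good, drop = FALSE], 2, stats::mad)
    keep <- vapply(seq_len(nrow(wins)), function(i) {
      i0 <- floor(wins$start_s[i] * rec$rate) + 1
      i1 <- min(nrow(rec$data), ceiling(wins$end_s[i] * rec$rate))
      seg <- rec$data[i0:i1, good, drop = FALSE]
      dev <- abs(sweep(seg, 2, med))
      lim <- artifact_z * pmax(rsd, 1e-12)
      all(sweep(dev, 2, lim, "<=") | rep(rsd == 0, each = nrow(seg)))
    }, logical(1))
    wins <- wins[keep, , drop = FALSE]
  }
  if (nrow(wins) == 0) warning("no qualifying SWS segment")
  rownames(wins) <- NULL
  structure(list(windows = wins, channels = good, dur_s = dur_s),
            class = "segment_set")
}

#' Total and normalized SWS duration
#'
#' Total duration counts SWS epochs at the 1-s epoch step; the normalized
#' duration divides by the scored (non-UNSCORED) session duration, giving a
#' scale-free fraction in [0, 1] comparable across sessions.
#'
#' @param hyp a `hypnogram`
#' @return list with `total_s` and `normalized`
#' @export
sws_duration <- function(hyp) {
  step <- if (length(hyp$epoch_time) > 1) diff(hyp$epoch_time[1:2]) else 1
  n_sws <- sum(hyp$label == "SWS")
  n_scored <- sum(hyp$label != "UNSCORED")
  list(total_s = n_sws * step,
       normalized = if (n_scored > 0) n_sws / n_scored else 0)
}

# Sample-index rows of a recording covered by a segment window.
segment_indices <- function(rec, start_s, end_s) {
  i0 <- floor(start_s * rec$rate) + 1
  i1 <- min(nrow(rec$data), floor(end_s * rec$rate))
  i0:i1
}
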