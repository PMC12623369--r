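# Preprocessing: bipolar referencing, anti-alias decimation to the LFP band,
# harmonic line-noise removal, and bad-channel screening.

#' Default adjacent-pair bipolar montage
#'
#' Pairs spatially adjacent channels within each region (1-2, 3-4, ...),
#' the standard local-reference practice when the acquisition montage gives
#' no other pairing.
#'
#' @param rec an [lfp_recording()]
#' @return data.frame with columns `anode`, `cathode`, `label`
#' @export
default_montage <- function(rec) {
  out <- lapply(split(rec$channels, rec$region[rec$channels]), function(chs) {
    n <- length(chs) - length(chs) %% 2
    if (n == 0) return(NULL)
    a <- chs[seq(1, n, by = 2)]
    c <- chs[seq(2, n, by = 2)]
    data.frame(anode = a, cathode = c, label = paste0(a, "-", c))
  })
  do.call(rbind, unname(out))
}

#' Apply a bipolar montage
#'
#' Each derived channel is the sample-wise difference anode - cathode. Pair
#' members must share a region; the derived channel inherits it. Subtracting
#' nearby channels suppresses common-mode and volume-conducted activity.
#'
#' @param rec an [lfp_recording()]
#' @param montage data.frame with columns `anode`, `cathode` and optionally
#'   `label`; defaults to [default_montage()].
#' @return an `lfp_recording` of the derived channels
#' @export
apply_bipolar <- function(rec, montage = default_montage(rec)) {
  stopifnot(all(c("anode", "cathode") %in% names(montage)))
  unknown <- setdiff(unique(c(montage$anode, montage$cathode)), rec$channels)
  if (length(unknown) > 0) {
    stop("unknown channel label(s) in montage: ",
         paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(montage$anode)) {
    stop("a channel appears twice as anode in the montage")
  }
  cross <- rec$region[montage$anode] != rec$region[montage$cathode]
  if (any(cross)) {
    stop("cross-region bipolar pair(s): ",
         paste(montage$anode[cross], montage$cathode[cross], sep = "-",
               collapse = ", "))
  }
  labels <- montage$label %||% paste0(montage$anode, "-", montage$cathode)
  data <- rec$data[, montage$anode, drop = FALSE] -
    rec$data[, montage$cathode, drop = FALSE]
  region <- stats::setNames(unname(rec$region[montage$anode]), labels)
  lfp_recording(data, rec$rate, channels = labels, region = region,
                start_time = rec$start_time)
}

# Windowed-sinc linear-phase FIR low-pass (Hamming window). `trans_hz` is
# the nominal transition width (Hamming factor 3.3/taps); the -6 dB point
# sits at `cutoff_hz`, stop-band attenuation is the Hamming-window 53 dB.
fir_lowpass <- function(fs, cutoff_hz, trans_hz) {
  order <- ceiling(3.3 * fs / trans_hz)
  order <- order + order %% 2          # even order -> odd, type-I kernel
  hs <- order / 2
  nn <- -hs:hs
  fc <- cutoff_hz / fs
  h <- 2 * fc * sinc(2 * fc * nn)
  w <- 0.54 + 0.46 * cos(pi * nn / hs)   # Hamming
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Band-stop stage at center f0: spectral inversion of a modulated low-pass
# whose -6 dB edges sit at f0 +/- width/2.
fir_bandstop <- function(fs, f0, width_hz, trans_hz) {
  lp <- fir_lowpass(fs, width_hz / 2, trans_hz)
  hs <- (length(lp) - 1) / 2
  nn <- -hs:hs
  bp <- 2 * lp * cos(2 * pi * f0 * nn / fs)
  h <- -bp
  h[hs + 1] <- h[hs + 1] + 1
  h
}

# Zero-phase application of an odd-length linear-phase FIR kernel: single
# FFT-convolution pass with exact group-delay compensation.
apply_fir_zerophase <- function(x, h) {
  Re(conv_same(x, h))
}

#' Low-pass filter and decimate a recording to the LFP band
#'
#' Anti-alias low-pass (zero phase, linear-phase FIR) at `cutoff_hz` followed
#' by integer-factor downsampling to `target_rate_hz`. An input already at the
#' target rate is low-pass filtered and passed through.
#'
#' @param rec an [lfp_recording()]
#' @param cutoff_hz low-pass cutoff (Hz); content above it is attenuated by
#'   >= 40 dB beyond the transition band.
#' @param target_rate_hz output sampling rate (Hz); must divide `rec$rate`.
#' @return an `lfp_recording` at `target_rate_hz`
#' @export
decimate_to_lfp <- function(rec, cutoff_hz = 300, target_rate_hz = 1000) {
  if (target_rate_hz > rec$rate) {
    stop("target rate (", target_rate_hz, " Hz) exceeds recording rate (",
         rec$rate, " Hz)")
  }
  if (rec$rate < 2 * cutoff_hz) {
    stop("recording rate must be at least twice the low-pass cutoff")
  }
  factor <- rec$rate / target_rate_hz
  if (abs(factor - round(factor)) > 1e-9) {
    stop("target rate must divide the recording rate by an integer factor")
  }
  factor <- round(factor)
  # passband edge ~cutoff, stopband edge ~cutoff + trans -> -53 dB by 400 Hz
  # for the default 300 Hz cutoff.
  trans <- cutoff_hz / 3
  h <- fir_lowpass(rec$rate, cutoff_hz + trans / 2, trans)
  filtered <- apply(rec$data, 2, apply_fir_zerophase, h = h)
  idx <- seq(1, nrow(filtered), by = factor)
  lfp_recording(filtered[idx, , drop = FALSE], target_rate_hz,
                channels = rec$channels, region = rec$region,
                start_time = rec$start_time)
}

#' Design the harmonic line-noise band-stop filter
#'
#' Cascade of linear-phase FIR band-stops (Hamming window) with
#' `stop_width_hz`-wide stop bands centered at `base_hz` and every harmonic
#' below Nyquist. The transition band (0.3 Hz) is steep enough that the
#' attenuation at each stop-band center exceeds `min_attenuation_db`.
#'
#' @param fs_hz sampling rate in Hz
#' @param base_hz line frequency (Hz), default 50
#' @param stop_width_hz nominal stop-band width (Hz, -6 dB edges)
#' @param min_attenuation_db required attenuation at each harmonic center
#' @param trans_hz transition width per edge-pair (Hz)
#' @param max_taps per-stage tap budget; the design errors out, reporting the
#'   achieved attenuation, if it cannot meet spec within the budget
#' @return object of class `fir_linefilter`: list with the combined kernel
#'   `h`, `fs`, `harmonics`, and achieved `attenuation_db` per harmonic
#' @export
design_line_filter <- function(fs_hz, base_hz = 50, stop_width_hz = 1,
                               min_attenuation_db = 53, trans_hz = 0.25,
                               max_taps = 40001) {
  if (fs_hz <= 2 * base_hz) stop("sampling rate must exceed twice base_hz")
  order <- ceiling(3.3 * fs_hz / trans_hz)
  order <- order + order %% 2
  if (order + 1 > max_taps) {
    # evaluate what the budget buys and refuse
    trans2 <- 3.3 * fs_hz / (max_taps - 1)
    h2 <- fir_bandstop(fs_hz, base_hz, stop_width_hz, trans2)
    ach <- -fir_response_db(h2, base_hz, fs_hz)
    stop(sprintf(paste0("cannot reach %g dB with %d taps: achieved %.1f dB ",
                        "at %g Hz"), min_attenuation_db, max_taps, ach,
                 base_hz))
  }
  harmonics <- seq(base_hz, fs_hz / 2 - stop_width_hz, by = base_hz)
  h <- 1
  for (f0 in harmonics) {
    hi <- fir_bandstop(fs_hz, f0, stop_width_hz, trans_hz)
    h <- if (identical(h, 1)) hi else conv_full(h, hi)
  }
  att <- -vapply(harmonics, function(f0) fir_response_db(h, f0, fs_hz), 0)
  if (any(att < min_attenuation_db)) {
    stop(sprintf("designed filter reaches only %.1f dB at %g Hz (need %g dB)",
                 min(att), harmonics[which.min(att)], min_attenuation_db))
  }
  structure(list(h = h, fs = fs_hz, base_hz = base_hz,
                 stop_width_hz = stop_width_hz, harmonics = harmonics,
                 attenuation_db = att),
            class = "fir_linefilter")
}

#' Magnitude response of an FIR kernel at given frequencies
#' @param h FIR kernel (impulse response)
#' @param freq_hz frequencies to evaluate (Hz)
#' @param fs sampling rate (Hz)
#' @return response in dB (0 dB = unit gain)
#' @export
fir_response_db <- function(h, freq_hz, fs) {
  n <- seq_along(h) - 1
  vapply(freq_hz, function(f) {
    20 * log10(Mod(sum(h * exp(-2i * pi * f * n / fs))))
  }, 0)
}

#' Apply the line-noise filter to a recording
#'
#' Zero-phase application (group-delay-compensated single pass) of the
#' cascade designed by [design_line_filter()].
#'
#' @param rec an [lfp_recording()] at the filter's sampling rate
#' @param filt a `fir_linefilter`; designed on the fly when omitted
#' @return the filtered recording
#' @export
apply_line_filter <- function(rec, filt = NULL) {
  filt <- filt %||% design_line_filter(rec$rate)
  if (abs(filt$fs - rec$rate) > 1e-9) {
    stop("filter designed for ", filt$fs, " Hz but recording is at ",
         rec$rate, " Hz")
  }
  data <- apply(rec$data, 2, apply_fir_zerophase, h = filt$h)
  lfp_recording(data, rec$rate, channels = rec$channels, region = rec$region,
                start_time = rec$start_time)
}

#' Screen channels for clipping and baseline drift
#'
#' A channel is flagged `clipped` when the fraction of samples sitting in runs
#' (>= `min_run` consecutive samples) within `rail_tol` of its observed
#' min/max rails exceeds `clip_frac_max`; genuinely clipped signals dwell at
#' the rail, whereas smooth oscillations only touch it instantaneously. A
#' channel is `drifting` when the periodogram power below `drift_cut_hz`
#' exceeds `drift_ratio_max` of total power.
#'
#' @param rec an [lfp_recording()]
#' @param clip_frac_max maximum tolerated clipped-sample fraction (default 0.02)
#' @param drift_ratio_max maximum tolerated sub-`drift_cut_hz` power ratio
#'   (default 0.5)
#' @param rail_tol rail window as a fraction of the signal range (default 0.001)
#' @param min_run minimum run length (samples) for rail dwell to count
#' @param drift_cut_hz drift band upper edge in Hz (default 0.5)
#' @return data.frame (`channel`, `flag`, `clip_fraction`, `drift_ratio`)
#'   with `flag` in `good`, `clipped`, `drifting`
#' @export
flag_bad_channels <- function(rec, clip_frac_max = 0.02,
                              drift_ratio_max = 0.5, rail_tol = 0.001,
                              min_run = 5, drift_cut_hz = 0.5) {
  n <- nrow(rec$data)
  if (n == 0) {
    warning("empty recording: all channels reported good")
    return(data.frame(channel = rec$channels, flag = "good",
                      clip_fraction = 0, drift_ratio = 0))
  }
  res <- lapply(rec$channels, function(ch) {
    x <- rec$data[, ch]
    rng <- max(x) - min(x)
    if (rng == 0) {
      return(data.frame(channel = ch, flag = "good", clip_fraction = 0,
                        drift_ratio = 0))
    }
    at_rail <- x >= max(x) - rail_tol * rng | x <= min(x) + rail_tol * rng
    runs <- logical_runs(at_rail)
    lens <- runs$end - runs$start + 1
    clip_frac <- sum(lens[lens >= min_run]) / n
    xc <- x - mean(x)
    p <- Mod(stats::fft(xc))^2
    nf <- floor(n / 2)
    f <- (1:nf) * rec$rate / n
    spec <- p[2:(nf + 1)]
    drift_ratio <- if (sum(spec) > 0) {
      sum(spec[f < drift_cut_hz]) / sum(spec)
    } else 0
    flag <- if (clip_frac > clip_frac_max) "clipped"
            else if (drift_ratio > drift_ratio_max) "drifting"
            else "good"
    data.frame(channel = ch, flag = flag, clip_fraction = clip_frac,
               drift_ratio = drift_ratio)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
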