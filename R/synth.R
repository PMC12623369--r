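# Ground-truthed synthetic LFP sessions: state-dependent spectra over a
# semi-Markov sleep-wake cycle, injectable phase coupling (PLV) and
# low-frequency-phase -> high-frequency-amplitude coupling (PAC), line noise
# and clipping artifacts. Every stage of the pipeline can be validated
# against the generator's known parameters.

#' Specification of a synthetic recording session
#'
#' Defaults emulate the study conditions the pipeline targets: two cortical
#' regions (S1, RFA) of 16 channels each at 1 kHz, a semi-Markov sleep-wake
#' cycle with mean dwell times WK 180 s / SWS 300 s / REM 90 s, 1/f
#' background, state-gated oscillators (delta-dominant SWS, theta-rich REM,
#' desynchronized WK), 50 Hz line noise with harmonics, and optional
#' clipping artifacts.
#'
#' @param duration_s session length in seconds
#' @param rate sampling rate in Hz (1000)
#' @param n_s1,n_rfa channels per region
#' @param dwell_s named mean dwell times in seconds for WK/SWS/REM
#' @param trans state transition matrix (rows WK/SWS/REM summing to 1)
#' @param background list: `exponent` (1/f slope) and `amp` (SD)
#' @param state_osc list per state of oscillator data.frames
#'   (`freq`, `amp`, `bw`)
#' @param plv_couplings list of `list(regions, freq, strength, amp)`; a
#'   shared oscillator phase is injected into every channel of the named
#'   region(s) with per-channel slow phase jitter whose SD is
#'   `sqrt(-ln(strength))` (wrapped-normal mapping), so the expected
#'   channel-pair PLV at `freq` equals `strength`.
#' @param pac_couplings list of `list(phase_region, amp_region, lf, ratio,
#'   depth, amp_lf, amp_hf)`; phase-region channels receive the LF
#'   oscillator, amplitude-region channels a carrier at `lf * ratio` whose
#'   envelope `(1 + depth * cos(phi_lf)) / (1 + depth)` keeps peak amplitude
#'   constant across modulation depths.
#' @param line_noise amplitude of the 50 Hz component (harmonics at 1/k);
#'   0 disables
#' @param artifacts list: `rate_per_min` (Poisson), `dur_s`, `magnitude`
#'   (clipping rail in robust SDs)
#' @param seed default RNG seed for [generate_session()]
#' @return list of class `session_spec`
#' @export
session_spec <- function(duration_s = 600, rate = 1000, n_s1 = 16,
                         n_rfa = 16,
                         dwell_s = c(WK = 180, SWS = 300, REM = 90),
                         trans = default_transitions(),
                         background = list(exponent = 1, amp = 1),
                         state_osc = default_state_oscillators(),
                         plv_couplings = list(),
                         pac_couplings = list(),
                         line_noise = 0.5,
                         artifacts = list(rate_per_min = 0, dur_s = 2,
                                          magnitude = 15),
                         seed = 1) {
  stopifnot(duration_s > 0, rate > 0, n_s1 >= 1, n_rfa >= 1)
  if (abs(sum(trans["WK", ]) - 1) > 1e-9 ||
      abs(sum(trans["SWS", ]) - 1) > 1e-9 ||
      abs(sum(trans["REM", ]) - 1) > 1e-9) {
    stop("transition matrix rows must sum to 1")
  }
  for (cp in plv_couplings) {
    if (cp$freq >= rate / 2) stop("PLV coupling frequency above Nyquist")
    stopifnot(cp$strength >= 0, cp$strength <= 1)
  }
  for (cp in pac_couplings) {
    if (cp$lf * cp$ratio >= rate / 2) {
      stop("PAC coupling high frequency above Nyquist")
    }
    stopifnot(cp$depth >= 0, cp$depth <= 1)
  }
  structure(list(duration_s = duration_s, rate = rate, n_s1 = n_s1,
                 n_rfa = n_rfa, dwell_s = dwell_s, trans = trans,
                 background = background, state_osc = state_osc,
                 plv_couplings = plv_couplings,
                 pac_couplings = pac_couplings, line_noise = line_noise,
                 artifacts = artifacts, seed = seed),
            class = "session_spec")
}

#' Default sleep-wake transition matrix
#' @return 3x3 matrix over WK/SWS/REM
#' @export
default_transitions <- function() {
  m <- matrix(c(0, 1, 0,
                0.65, 0, 0.35,
                0.8, 0.2, 0),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("WK", "SWS", "REM"),
                              c("WK", "SWS", "REM")))
  m
}

#' Default state-dependent oscillator profiles
#'
#' Delta-dominant SWS, theta-rich REM, desynchronized (broadband) WK -- the
#' structure the staging spectral ratios are designed to separate.
#' @return named list of data.frames (`freq`, `amp`, `bw`)
#' @export
default_state_oscillators <- function() {
  list(
    WK = data.frame(freq = c(6.5, 35), amp = c(0.4, 1.3), bw = c(1.5, 8)),
    SWS = data.frame(freq = c(2, 12), amp = c(3, 0.5), bw = c(0.8, 2)),
    REM = data.frame(freq = c(6.5, 40), amp = c(2.5, 0.4), bw = c(1, 8))
  )
}

# Phase-diffusing oscillator phase: linewidth `bw` (Hz) via per-sample
# increment variance 2*pi*bw/fs.
diffuse_phase <- function(n, freq, fs, bw) {
  cumsum(2 * pi * freq / fs + sqrt(2 * pi * bw / fs) * stats::rnorm(n)) +
    stats::runif(1, 0, 2 * pi)
}

# 1/f^exponent background noise with unit SD, by FFT spectral shaping.
background_noise <- function(n, exponent) {
  w <- stats::rnorm(n)
  if (exponent == 0) return(w)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))            # avoid DC blowup
  f <- pmin(f, n - f + 1)              # symmetric about Nyquist
  g <- f^(-exponent / 2)
  g[1] <- 0
  x <- Re(stats::fft(W * g, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Slowly varying zero-mean Gaussian jitter with stationary SD `sd` and
# correlation time ~`tau_s` (Gaussian-kernel smoothing of white noise).
slow_jitter <- function(n, fs, sd, tau_s = 0.5) {
  if (sd == 0) return(rep(0, n))
  hs <- ceiling(3 * tau_s * fs)
  t <- (-hs:hs) / fs
  k <- exp(-t^2 / (2 * tau_s^2))
  e <- Re(conv_same(stats::rnorm(n), k / sqrt(sum(k^2))))
  e * sd / stats::sd(e)
}

# Semi-Markov state sequence at 1-s resolution: gamma dwell times
# (shape 2) around the mean dwell, then a transition-matrix jump.
sample_states <- function(duration_s, dwell_s, trans) {
  states <- character(0)
  cur <- "WK"
  while (length(states) < duration_s) {
    d <- max(5, round(stats::rgamma(1, shape = 2,
                                    scale = dwell_s[cur] / 2)))
    states <- c(states, rep(cur, d))
    cur <- sample(colnames(trans), 1, prob = trans[cur, ])
  }
  states[1:duration_s]
}

# Per-sample gate for a state: smoothed indicator with 1-s Hann ramps.
state_gate <- function(state_sec, state, fs) {
  ind <- rep(as.numeric(state_sec == state), each = fs)
  k <- hann_symmetric(fs + 1)
  Re(conv_same(ind, k / sum(k)))
}

#' Generate a synthetic session with known ground truth
#'
#' Signal per channel = 1/f background + state-gated oscillators
#' + injected coupling terms + line noise + clipping artifacts; fully
#' reproducible from `seed`.
#'
#' @param spec a [session_spec()]
#' @param seed RNG seed (defaults to `spec$seed`)
#' @return list: `recording` (an [lfp_recording()]) and `truth` (list with
#'   `hypnogram` aligned to the staging epoch grid, `state_sec`,
#'   `plv_couplings`, `pac_couplings`, `artifact_windows`, `region_of`,
#'   `spec`)
#' @export
generate_session <- function(spec, seed = spec$seed) {
  fs <- spec$rate
  n <- round(spec$duration_s * fs)
  chs <- c(paste0("s1_", seq_len(spec$n_s1)),
           paste0("rfa_", seq_len(spec$n_rfa)))
  region <- stats::setNames(rep(c("S1", "RFA"), c(spec$n_s1, spec$n_rfa)),
                            chs)
  out <- with_seed(seed, {
    state_sec <- sample_states(spec$duration_s, spec$dwell_s, spec$trans)
    gates <- lapply(c("WK", "SWS", "REM"), state_gate,
                    state_sec = state_sec, fs = fs)
    names(gates) <- c("WK", "SWS", "REM")
    data <- matrix(0, n, length(chs), dimnames = list(NULL, chs))
    for (ch in seq_along(chs)) {
      x <- if (spec$background$amp > 0) {
        spec$background$amp * background_noise(n, spec$background$exponent)
      } else rep(0, n)
      for (st in names(spec$state_osc)) {
        osc <- spec$state_osc[[st]]
        for (i in seq_len(nrow(osc))) {
          phi <- diffuse_phase(n, osc$freq[i], fs, osc$bw[i])
          x <- x + osc$amp[i] * gates[[st]] * cos(phi)
        }
      }
      data[, ch] <- x
    }
    for (cp in spec$plv_couplings) {
      targets <- chs[region %in% cp$regions]
      phi <- diffuse_phase(n, cp$freq, fs, cp$bw %||% 0.5)
      sig <- sqrt(-log(max(cp$strength, 1e-12)))
      amp <- cp$amp %||% 3
      for (ch in targets) {
        eta <- slow_jitter(n, fs, sig)
        data[, ch] <- data[, ch] + amp * cos(phi + eta)
      }
    }
    for (cp in spec$pac_couplings) {
      hf <- cp$lf * cp$ratio
      phi_lf <- diffuse_phase(n, cp$lf, fs, cp$bw_lf %||% 0.3)
      env <- (1 + cp$depth * cos(phi_lf)) / (1 + cp$depth)
      amp_lf <- cp$amp_lf %||% 2
      amp_hf <- cp$amp_hf %||% 2
      for (ch in chs[region == cp$phase_region]) {
        data[, ch] <- data[, ch] + amp_lf * cos(phi_lf)
      }
      for (ch in chs[region == cp$amp_region]) {
        phi_hf <- diffuse_phase(n, hf, fs, cp$bw_hf %||% hf / 20)
        data[, ch] <- data[, ch] + amp_hf * env * cos(phi_hf)
      }
    }
    if (spec$line_noise > 0) {
      t <- (0:(n - 1)) / fs
      for (k in 1:3) {
        f0 <- 50 * k
        if (f0 < fs / 2) {
          data <- data + (spec$line_noise / k) *
            sin(2 * pi * f0 * t + stats::runif(1, 0, 2 * pi))
        }
      }
    }
    art <- data.frame(start_s = numeric(0), end_s = numeric(0))
    if (spec$artifacts$rate_per_min > 0) {
      n_art <- stats::rpois(1, spec$artifacts$rate_per_min *
                              spec$duration_s / 60)
      if (n_art > 0) {
        starts <- sort(stats::runif(n_art, 0,
                                    spec$duration_s - spec$artifacts$dur_s))
        art <- data.frame(start_s = starts,
                          end_s = starts + spec$artifacts$dur_s)
        for (i in seq_len(nrow(art))) {
          i0 <- floor(art$start_s[i] * fs) + 1
          i1 <- min(n, ceiling(art$end_s[i] * fs))
          tt <- (i0:i1) / fs
          for (ch in seq_along(chs)) {
            rail <- spec$artifacts$magnitude * stats::mad(data[, ch])
            data[i0:i1, ch] <- rail * sign(sin(2 * pi * 5 * tt) + 1e-9)
          }
        }
      }
    }
    list(data = data, state_sec = state_sec, artifact_windows = art)
  })
  rec <- lfp_recording(out$data, fs, channels = chs, region = region)
  # truth hypnogram on the staging epoch grid (2-s windows, 1-s step):
  # epoch centers at 1, 2, ..., duration-1 s; label = state at the center.
  centers <- seq_len(spec$duration_s - 1)
  hyp <- structure(
    list(epoch_time = centers,
         label = factor(out$state_sec[centers + 1],
                        levels = c("WK", "SWS", "REM", "UNSCORED"))),
    class = "hypnogram")
  list(recording = rec,
       truth = list(hypnogram = hyp, state_sec = out$state_sec,
                    plv_couplings = spec$plv_couplings,
                    pac_couplings = spec$pac_couplings,
                    artifact_windows = out$artifact_windows,
                    region_of = region, spec = spec))
}

#' Generate a multi-animal, multi-condition synthetic study
#'
#' Mirrors the target design: a control group recorded once (condition
#' `"NOLESION"`) and a lesion group recorded at two time points (`"D7"`,
#' `"D14"`). Per-animal random effects multiply PAC modulation depths and
#' SWS dwell times (log-normal); per-condition effects override coupling
#' parameters to create positive-control studies.
#'
#' @param base_spec the [session_spec()] all sessions start from
#' @param n_nolesion,n_lesion animals per group
#' @param condition_effects named list (`NOLESION`, `D7`, `D14`) of lists
#'   with optional elements `pac_depth` (replaces the depth of every PAC
#'   coupling) and `plv_strength`
#' @param animal_sd list: `pac_depth` and `sws_dwell` log-normal SDs of the
#'   per-animal multipliers
#' @param seed study seed; session seeds are derived deterministically
#' @return list: `sessions` (list of `list(animal, condition, recording,
#'   truth)`), `truth_table` (data.frame of injected parameters per session)
#' @export
make_study <- function(base_spec, n_nolesion = 5, n_lesion = 4,
                       condition_effects = list(),
                       animal_sd = list(pac_depth = 0.1, sws_dwell = 0.1),
                       seed = 1) {
  stopifnot(n_nolesion >= 2, n_lesion >= 2)
  plan <- rbind(
    data.frame(animal = paste0("ctl", seq_len(n_nolesion)),
               condition = "NOLESION"),
    expand.grid(animal = paste0("les", seq_len(n_lesion)),
                condition = c("D7", "D14"), stringsAsFactors = FALSE)
  )
  animals <- unique(plan$animal)
  re <- with_seed(seed, data.frame(
    animal = animals,
    pac_mult = exp(stats::rnorm(length(animals), 0, animal_sd$pac_depth)),
    dwell_mult = exp(stats::rnorm(length(animals), 0, animal_sd$sws_dwell))))
  sessions <- vector("list", nrow(plan))
  truth_rows <- list()
  for (i in seq_len(nrow(plan))) {
    sp <- base_spec
    an <- plan$animal[i]; cond <- plan$condition[i]
    mult <- re[re$animal == an, ]
    sp$dwell_s["SWS"] <- sp$dwell_s["SWS"] * mult$dwell_mult
    eff <- condition_effects[[cond]] %||% list()
    sp$pac_couplings <- lapply(sp$pac_couplings, function(cp) {
      d <- (eff$pac_depth %||% cp$depth) * mult$pac_mult
      cp$depth <- min(1, d)
      cp
    })
    sp$plv_couplings <- lapply(sp$plv_couplings, function(cp) {
      cp$strength <- min(1, eff$plv_strength %||% cp$strength)
      cp
    })
    sess_seed <- (seed * 10007 + i * 101) %% 2147483647
    g <- generate_session(sp, seed = sess_seed)
    sessions[[i]] <- list(animal = an, condition = cond,
                          recording = g$recording, truth = g$truth)
    depth <- if (length(sp$pac_couplings)) {
      sp$pac_couplings[[1]]$depth
    } else NA_real_
    strength <- if (length(sp$plv_couplings)) {
      sp$plv_couplings[[1]]$strength
    } else NA_real_
    truth_rows[[i]] <- data.frame(animal = an, condition = cond,
                                  seed = sess_seed, pac_depth = depth,
                                  plv_strength = strength,
                                  sws_dwell_s = unname(sp$dwell_s["SWS"]))
  }
  list(sessions = sessions, truth_table = do.call(rbind, truth_rows))
}
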