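# Spectral-ratio state maps, clustering, SWS segment extraction.

test_that("spectral ratios reflect band placement of pure tones", {
  rec <- make_rec(lo = sine(2, 30), hi = sine(40, 30),
                  region = c(lo = "S1", hi = "RFA"))
  r <- spectral_ratios(rec)
  expect_equal(diff(r$epoch_time[1:2]), 1)
  # 2 Hz: all power below every numerator edge -> both ratios ~ 1
  expect_gt(min(r$ratio1[, "lo"]), 0.99)
  expect_gt(min(r$ratio2[, "lo"]), 0.99)
  # 40 Hz: inside 0.5-55 but outside 0.5-20 -> ratio1 ~ 0
  expect_lt(max(r$ratio1[, "hi"]), 0.05)
  # bounded in (0, 1]
  expect_true(all(r$ratio1 > 0 & r$ratio1 <= 1))
  # all-zero window -> NA ratios
  z <- make_rec(z = rep(0, 5000), region = c(z = "S1"))
  expect_true(all(is.na(spectral_ratios(z)$ratio1)))
})

test_that("ratios match a direct periodogram-integration oracle on 1/f noise", {
  set.seed(10)
  n <- 30000
  fs <- 1000
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- pmin(c(1, 1:(n - 1)), c(1, (n - 1):1))
  x <- Re(stats::fft(W * f^-0.5 * c(0, rep(1, n - 1)), inverse = TRUE)) / n
  rec <- make_rec(x = x, region = c(x = "S1"))
  r <- spectral_ratios(rec)
  # oracle: literal Hann-tapered periodogram integration for a few windows
  for (ep in c(1, 10, 25)) {
    s <- (ep - 1) * fs + 1
    seg <- x[s:(s + 2 * fs - 1)]
    w2 <- 0.5 * (1 - cos(2 * pi * (0:(2 * fs - 1)) / (2 * fs)))
    P <- Mod(stats::fft(seg * w2))^2
    fr <- (0:(2 * fs - 1)) * fs / (2 * fs)
    bp <- function(lo, hi) sum(P[fr >= lo & fr <= hi & fr <= fs / 2])
    expect_equal(unname(r$ratio1[ep, 1]), bp(0.5, 20) / bp(0.5, 55),
                 tolerance = 0.01)
    expect_equal(unname(r$ratio2[ep, 1]), bp(0.5, 4.5) / bp(0.5, 9),
                 tolerance = 0.01)
  }
})

test_that("state map PC orientation follows the cross-channel mean and smoothing preserves the mean", {
  set.seed(11)
  n_ep <- 400
  base <- stats::filter(rnorm(n_ep), rep(1 / 5, 5), circular = TRUE)
  ratios <- list(epoch_time = seq_len(n_ep),
                 ratio1 = cbind(a = base + rnorm(n_ep, 0, 0.05),
                                b = base + rnorm(n_ep, 0, 0.05)),
                 ratio2 = cbind(a = -base + rnorm(n_ep, 0, 0.05),
                                b = -base + rnorm(n_ep, 0, 0.05)))
  sm <- build_state_map(ratios)
  # orientation rule: the smoothed PC correlates positively (and strongly)
  # with the cross-channel mean even though ratio2 channels are the
  # negative of ratio1 channels
  expect_gt(stats::cor(sm$y, rowMeans(ratios$ratio1)), 0.5)
  expect_gt(stats::cor(sm$x, rowMeans(ratios$ratio2)), 0.5)
  # unit-sum kernel: smoothing is mean-preserving to 1e-6
  pc <- sleeplfp:::pc1_oriented(ratios$ratio1)
  sm_pc <- sleeplfp:::smooth_circular(pc, sleeplfp:::hann_symmetric(21))
  expect_equal(mean(sm_pc), mean(pc), tolerance = 1e-6)
  # identical channels: map collapses onto the common series
  r2 <- list(epoch_time = seq_len(n_ep),
             ratio1 = cbind(a = base, b = base),
             ratio2 = cbind(a = base, b = base))
  sm2 <- build_state_map(r2)
  expect_gt(abs(stats::cor(sm2$x, sm2$y)), 0.999)
})

test_that("clustering labels well-separated blobs by position and rejects degenerate maps", {
  set.seed(12)
  n <- 200
  blob <- function(cx, cy) cbind(rnorm(n, cx, 0.03), rnorm(n, cy, 0.03))
  pts <- rbind(blob(0.9, 0.8),   # high x: SWS
               blob(0.3, 0.8),   # low x, high y: REM
               blob(0.5, 0.3))   # low y: WK
  truth <- rep(c("SWS", "REM", "WK"), each = n)
  map <- structure(list(epoch_time = seq_len(3 * n), x = pts[, 1],
                        y = pts[, 2]), class = "state_map")
  hyp <- cluster_states(map)
  expect_equal(mean(as.character(hyp$label) == truth), 1)
  # single blob -> no real structure -> all UNSCORED
  map1 <- structure(list(epoch_time = seq_len(n), x = rnorm(n),
                         y = rnorm(n)), class = "state_map")
  expect_true(all(cluster_states(map1)$label == "UNSCORED"))
  # zero-variance map -> all UNSCORED
  map0 <- structure(list(epoch_time = 1:50, x = rep(1, 50), y = rep(1, 50)),
                    class = "state_map")
  expect_true(all(cluster_states(map0)$label == "UNSCORED"))
})

test_that("SWS runs are tiled into non-overlapping 120-s windows", {
  set.seed(13)
  rec <- make_rec(a = rnorm(650 * 1000), b = rnorm(650 * 1000),
                  region = c(a = "S1", b = "RFA"))
  # 600 s of contiguous SWS at the start -> 5 windows
  hyp <- make_hyp(c(rep("SWS", 599), rep("WK", 50)))
  seg <- extract_sws_segments(hyp, rec)
  expect_equal(nrow(seg$windows), 5)
  expect_true(all(seg$windows$end_s - seg$windows$start_s == 120))
  expect_true(all(diff(seg$windows$start_s) >= 120))
  # 230 s contiguous -> 1 window
  hyp2 <- make_hyp(c(rep("SWS", 229), rep("WK", 420)))
  expect_equal(nrow(extract_sws_segments(hyp2, rec)$windows), 1)
  # too short -> empty with warning
  hyp3 <- make_hyp(rep(c("SWS", "WK"), length.out = 649))
  expect_warning(s3 <- extract_sws_segments(hyp3, rec), "no qualifying")
  expect_equal(nrow(s3$windows), 0)
})

test_that("windows containing amplitude artifacts are dropped and flagged channels excluded", {
  set.seed(14)
  x <- rnorm(650 * 1000)
  x[(150 * 1000):(151 * 1000)] <- 40      # clipping burst inside window 2
  rec <- make_rec(a = x, b = rnorm(650 * 1000),
                  region = c(a = "S1", b = "RFA"))
  hyp <- make_hyp(c(rep("SWS", 599), rep("WK", 50)))
  seg <- extract_sws_segments(hyp, rec)
  expect_equal(nrow(seg$windows), 4)
  expect_false(any(seg$windows$start_s <= 150 & seg$windows$end_s >= 151))
  # flagged channel is excluded from both screening and the channel list
  q <- data.frame(channel = c("a", "b"), flag = c("clipped", "good"))
  seg2 <- extract_sws_segments(hyp, rec, quality = q)
  expect_equal(seg2$channels, "b")
  expect_equal(nrow(seg2$windows), 5)
})

test_that("SWS duration is step-weighted and normalized by scored time", {
  expect_equal(sws_duration(make_hyp(rep("SWS", 100)))$normalized, 1)
  expect_equal(sws_duration(make_hyp(rep("WK", 100)))$normalized, 0)
  expect_equal(sws_duration(make_hyp(rep(c("SWS", "WK"), 50)))$normalized,
               0.5)
  h <- sws_duration(make_hyp(c(rep("SWS", 30), rep("REM", 10),
                               rep("UNSCORED", 10))))
  expect_equal(h$total_s, 30)
  expect_equal(h$normalized, 0.75)
})
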