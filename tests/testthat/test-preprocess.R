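# Bipolar referencing, decimation, line-noise filtering, channel screening.

test_that("bipolar derivation subtracts references and rejects bad montages", {
  set.seed(1)
  s <- sine(5, 4)
  rec <- make_rec(c1 = s, c2 = rep(0, length(s)), c3 = rnorm(length(s)),
                  c4 = rnorm(length(s)),
                  region = c(c1 = "S1", c2 = "S1", c3 = "RFA", c4 = "RFA"))
  # self-difference is exactly zero
  m0 <- data.frame(anode = "c1", cathode = "c1")
  expect_true(all(apply_bipolar(rec, m0)$data == 0))
  # zero reference leaves the signal untouched
  m1 <- data.frame(anode = "c1", cathode = "c2")
  expect_equal(unname(apply_bipolar(rec, m1)$data[, 1]), s)
  # region metadata inherited
  der <- apply_bipolar(rec, data.frame(anode = c("c1", "c3"),
                                       cathode = c("c2", "c4")))
  expect_equal(unname(der$region), c("S1", "RFA"))
  expect_equal(ncol(der$data), 2)
  # errors: unknown channel, cross-region pair, duplicated anode
  expect_error(apply_bipolar(rec, data.frame(anode = "zz", cathode = "c1")),
               "unknown channel")
  expect_error(apply_bipolar(rec, data.frame(anode = "c1", cathode = "c3")),
               "cross-region")
  expect_error(apply_bipolar(rec, data.frame(anode = c("c1", "c1"),
                                             cathode = c("c2", "c2"))),
               "twice as anode")
})

test_that("bipolar derivation removes additive common-mode drift", {
  set.seed(2)
  n <- 8000
  drift <- cumsum(rnorm(n, 0, 0.05))      # shared slow common mode
  a <- drift + rnorm(n)
  b <- drift + rnorm(n)
  rec <- make_rec(a = a, b = b, region = c(a = "S1", b = "S1"))
  der <- apply_bipolar(rec, data.frame(anode = "a", cathode = "b"))
  expect_lt(abs(stats::cor(der$data[, 1], drift)), 0.05)
})

test_that("decimation preserves the passband and suppresses 400 Hz", {
  fs <- 25000
  t <- (1:(4 * fs)) / fs
  rec <- make_rec(lo = sin(2 * pi * 10 * t), hi = sin(2 * pi * 400 * t),
                  fs = fs, region = c(lo = "S1", hi = "RFA"))
  d <- decimate_to_lfp(rec)
  expect_equal(d$rate, 1000)
  expect_equal(nrow(d$data), 4000)
  mid <- 500:3500                          # avoid filter edge transients
  expect_lt(abs(max(abs(d$data[mid, "lo"])) - 1), 0.01)
  expect_lt(sqrt(mean(d$data[mid, "hi"]^2)) / sqrt(0.5), 0.01)
  # already at target rate: low-pass pass-through
  r1k <- make_rec(x = sine(10, 4), region = c(x = "S1"))
  p <- decimate_to_lfp(r1k)
  expect_equal(p$rate, 1000)
  expect_equal(nrow(p$data), nrow(r1k$data))
  expect_lt(max(abs(p$data[500:3500, 1] - r1k$data[500:3500, 1])), 0.02)
  # errors
  expect_error(decimate_to_lfp(r1k, target_rate_hz = 2000), "exceeds")
  expect_error(decimate_to_lfp(make_rec(x = sine(10, 2), fs = 1500,
                                        region = c(x = "S1"))),
               "integer factor")
})

test_that("decimation is Parseval-consistent over 0-300 Hz", {
  set.seed(3)
  fs <- 5000
  x <- rnorm(60 * fs)
  rec <- make_rec(x = x, fs = fs, region = c(x = "S1"))
  d <- decimate_to_lfp(rec)
  mid_in <- (5 * fs):(55 * fs)
  mid_out <- 5000:55000
  pin <- welch_psd(x[mid_in], fs_hz = fs)
  pout <- welch_psd(d$data[mid_out, 1], fs_hz = 1000)
  df_in <- diff(pin$freq[1:2]); df_out <- diff(pout$freq[1:2])
  p_in <- sum(pin$power[pin$freq <= 300]) * df_in
  p_out <- sum(pout$power[pout$freq <= 300]) * df_out
  expect_lt(abs(p_out / p_in - 1), 0.05)
})

test_that("line filter meets the 53 dB / 1 Hz harmonic band-stop spec", {
  lf <- line_filter_1k()
  # harmonics at 50, 100, ..., 450 Hz all present
  expect_equal(lf$harmonics, seq(50, 450, by = 50))
  resp <- fir_response_db(lf$h, lf$harmonics, 1000)
  expect_true(all(resp <= -53))
  expect_lte(fir_response_db(lf$h, 150, 1000), -53)
  # passband flat within 1 dB
  expect_lt(max(abs(fir_response_db(lf$h, c(10, 25, 40, 60, 75), 1000))), 1)
  # unattainable budget errors with achieved attenuation
  expect_error(design_line_filter(1000, max_taps = 501), "achieved")
})

test_that("line filter notches white noise by >= 53 dB without touching 10-40 Hz", {
  set.seed(4)
  lf <- line_filter_1k()
  n <- 450000
  x <- rnorm(n)
  y <- apply_fir_zerophase(x, lf$h)
  mid <- 130000:320000                      # beyond the kernel transient
  px <- welch_psd(x[mid], 1000, nperseg = 65536)
  py <- welch_psd(y[mid], 1000, nperseg = 65536)
  b50 <- px$freq >= 49.7 & px$freq <= 50.3
  b_pass <- px$freq >= 10 & px$freq <= 40
  expect_lt(10 * log10(mean(py$power[b50]) / mean(px$power[b50])), -53)
  expect_lt(abs(10 * log10(mean(py$power[b_pass]) /
                             mean(px$power[b_pass]))), 1)
})

test_that("channel screening flags clipping and drift but passes clean sines", {
  fs <- 1000
  sq <- sign(sine(5, 10))                   # saturating square wave
  cl <- sine(10, 10)
  ramp_mix <- sine(10, 10, amp = 0.5) + 10 * sine(0.05, 10)
  rec <- make_rec(sq = sq, ok = cl, dr = ramp_mix,
                  region = c(sq = "S1", ok = "S1", dr = "RFA"))
  q <- flag_bad_channels(rec)
  expect_equal(q$flag[q$channel == "sq"], "clipped")
  expect_gt(q$clip_fraction[q$channel == "sq"], 0.9)
  expect_equal(q$flag[q$channel == "ok"], "good")
  expect_equal(q$flag[q$channel == "dr"], "drifting")
  expect_gt(q$drift_ratio[q$channel == "dr"], 0.5)
  # empty recording: all good with a warning
  empty <- lfp_recording(matrix(numeric(0), 0, 1, dimnames = list(NULL, "a")),
                         1000, region = c(a = "S1"))
  expect_warning(q0 <- flag_bad_channels(empty), "empty")
  expect_equal(q0$flag, "good")
})
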