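# Synthetic session generator: determinism, spectral ground truth, coupling
# calibration plumbing, artifacts, study assembly.

test_that("generation is fully reproducible from the seed", {
  sp <- quiet_spec(duration_s = 40)
  g1 <- generate_session(sp, seed = 7)
  g2 <- generate_session(sp, seed = 7)
  expect_identical(g1$recording$data, g2$recording$data)
  expect_identical(g1$truth$state_sec, g2$truth$state_sec)
  g3 <- generate_session(sp, seed = 8)
  expect_false(identical(g1$recording$data, g3$recording$data))
  # byte-identical files from the same seed
  p1 <- file.path(tempdir(), "sess_a"); p2 <- file.path(tempdir(), "sess_b")
  write_recording(g1$recording, p1); write_recording(g2$recording, p2)
  expect_identical(readBin(paste0(p1, ".bin"), "raw", 1e6),
                   readBin(paste0(p2, ".bin"), "raw", 1e6))
})

test_that("truth hypnogram aligns with the staging epoch grid", {
  sp <- quiet_spec(duration_s = 60, n_s1 = 2, n_rfa = 2)
  g <- generate_session(sp, seed = 9)
  r <- spectral_ratios(g$recording)
  expect_equal(g$truth$hypnogram$epoch_time, r$epoch_time)
  expect_equal(length(g$truth$state_sec), 60)
})

test_that("the 1/f background matches the requested spectral exponent", {
  for (expo in c(1, 2)) {
    sp <- session_spec(duration_s = 240, n_s1 = 1, n_rfa = 1,
                       line_noise = 0, state_osc = list(),
                       background = list(exponent = expo, amp = 1))
    g <- generate_session(sp, seed = 10 + expo)
    p <- welch_psd(g$recording$data[, 1], 1000, nperseg = 8192)
    sel <- p$freq >= 2 & p$freq <= 80
    slope <- stats::coef(stats::lm(log(p$power[sel]) ~
                                     log(p$freq[sel])))[2]
    expect_lt(abs(slope + expo), 0.2)
  }
})

test_that("deterministic shared phase with zero jitter gives PLV ~ 1", {
  sp <- session_spec(duration_s = 40, n_s1 = 1, n_rfa = 1, line_noise = 0,
                     state_osc = list(),
                     background = list(exponent = 1, amp = 0.001),
                     plv_couplings = list(list(regions = c("S1", "RFA"),
                                               freq = 3, strength = 1)))
  g <- generate_session(sp, seed = 12)
  wt <- morlet_transform(g$recording$data, 3, 1000)
  P <- sleeplfp:::plv_matrix(wt$coef[wt$valid, ])
  expect_gt(P[1, 2], 0.99)
})

test_that("nPAC of an uncoupled session is near 1 at the tested cell", {
  gr <- data.frame(lf_hz = 5.9, ratio = 7, hf_hz = 41.3, valid = TRUE)
  v <- sapply(1:4, function(s) {
    g <- generate_session(quiet_spec(duration_s = 100), seed = 20 + s)
    sleeplfp:::pac_cells(g$recording$data[, 1], g$recording$data[, 2], gr,
                         1000, n_surrogates = 50, seed = s)$npac
  })
  expect_gt(mean(v), 0.5)
  expect_lt(mean(v), 1.6)
})

test_that("couplings above Nyquist are rejected", {
  expect_error(session_spec(plv_couplings = list(
    list(regions = c("S1", "RFA"), freq = 600, strength = 0.5))),
    "Nyquist")
  expect_error(session_spec(pac_couplings = list(
    list(phase_region = "S1", amp_region = "RFA", lf = 10, ratio = 100,
         depth = 0.5))),
    "Nyquist")
})

test_that("injected clipping bursts are the windows the artifact screen drops", {
  sp <- session_spec(duration_s = 400, n_s1 = 2, n_rfa = 2, line_noise = 0,
                     dwell_s = c(WK = 10, SWS = 1e6, REM = 10),
                     artifacts = list(rate_per_min = 0.8, dur_s = 2,
                                      magnitude = 20))
  g <- generate_session(sp, seed = 30)
  art <- g$truth$artifact_windows
  expect_gt(nrow(art), 0)
  seg <- extract_sws_segments(g$truth$hypnogram, g$recording, dur_s = 60)
  # reconstruct the candidate tiling of the (single) SWS run
  sws_ep <- g$truth$hypnogram$epoch_time[g$truth$hypnogram$label == "SWS"]
  t0 <- max(0, min(sws_ep) - 1)
  t1 <- min(400, max(sws_ep) + 1)
  all_windows <- t0 + 60 * (0:(floor((t1 - t0) / 60) - 1))
  overlaps <- function(s, e) any(art$start_s < e & art$end_s > s)
  hit <- vapply(all_windows, function(s) overlaps(s, s + 60), logical(1))
  kept <- all_windows %in% seg$windows$start_s
  # windows overlapping an injected artifact are exactly those dropped
  expect_true(all(!kept[hit]))
  expect_gte(mean(kept[!hit]), 0.9)
})

test_that("study assembly applies condition effects and per-animal random effects", {
  base <- quiet_spec(duration_s = 30,
                     pac_couplings = list(list(phase_region = "S1",
                                               amp_region = "RFA",
                                               lf = 5.9, ratio = 7,
                                               depth = 0.4)))
  st <- make_study(base, n_nolesion = 2, n_lesion = 2,
                   condition_effects = list(D7 = list(pac_depth = 0.6),
                                            D14 = list(pac_depth = 0.2)),
                   seed = 3)
  tt <- st$truth_table
  expect_equal(nrow(tt), 2 + 2 * 2)
  expect_setequal(unique(tt$condition), c("NOLESION", "D7", "D14"))
  # condition effect applied on top of the animal multiplier
  d7 <- tt[tt$condition == "D7", ]; d14 <- tt[tt$condition == "D14", ]
  d7 <- d7[order(d7$animal), ]; d14 <- d14[order(d14$animal), ]
  expect_true(all(d7$pac_depth > d14$pac_depth))
  expect_equal(d7$pac_depth / d14$pac_depth, rep(3, 2), tolerance = 1e-9)
  # animals differ through their random effects
  expect_gt(stats::sd(tt$pac_depth[tt$condition == "D7"]), 0)
  # sessions reproducible from the study seed
  st2 <- make_study(base, n_nolesion = 2, n_lesion = 2,
                    condition_effects = list(D7 = list(pac_depth = 0.6),
                                             D14 = list(pac_depth = 0.2)),
                    seed = 3)
  expect_identical(st$sessions[[3]]$recording$data,
                   st2$sessions[[3]]$recording$data)
})
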