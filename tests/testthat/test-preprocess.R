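fs <- 1500
t_ax <- (0:8999) / fs
central <- 3000:6000

test_that("high-pass removes DC and preserves the passband", {
  rec <- const_rec(rep(100, 9000), fs = fs)
  out <- highpass(rec)
  expect_lt(max(abs(out$samples[1000:8000, ])), 1)

  rec100 <- const_rec(sin(2 * pi * 100 * t_ax), fs = fs)
  out100 <- highpass(rec100)
  expect_lt(abs(max(abs(out100$samples[central, 1])) - 1), 0.05)

  # stopband attenuation matches the designed response at 5 Hz
  rec5 <- const_rec(sin(2 * pi * 5 * t_ax), fs = fs)
  out5 <- highpass(rec5)
  gain_meas <- max(abs(out5$samples[central, 1]))
  gain_design <- highpass_response(filter_spec(), fs, 5)
  expect_lt(abs(gain_meas - gain_design) / gain_design, 0.05)

  expect_error(highpass(rec, filter_spec(highpass_cutoff_hz = 800)), "Nyquist")
  expect_error(filter_spec(fir_order = 31), "even")
})

test_that("high-pass filtering is linear and applied identically per channel", {
  set.seed(21)
  x <- rnorm(6000); y <- rnorm(6000)
  a <- 2.5; b <- -1.3
  rec <- const_rec(a * x + b * y, fs = fs,
                   per_channel = c(list(x, y, a * x + b * y), rep(list(x), 7)))
  out <- highpass(rec)
  expect_equal(out$samples[, 3], a * out$samples[, 1] + b * out$samples[, 2],
               tolerance = 1e-9)
  # identical input -> identical output on every channel
  expect_equal(out$samples[, 4], out$samples[, 1], tolerance = 1e-12)
})

test_that("notch is selective: flagged channels filtered, others untouched", {
  s50 <- sin(2 * pi * 50 * t_ax)
  rec <- const_rec(s50, fs = fs)
  rec$notch_flags["TA_r"] <- TRUE
  out <- notch(rec)
  expect_lt(max(abs(out$samples[central, "TA_r"])), 0.05)
  expect_identical(out$samples[, "PL_r"], rec$samples[, "PL_r"])

  rec100 <- const_rec(sin(2 * pi * 100 * t_ax), fs = fs)
  rec100$notch_flags["TA_r"] <- TRUE
  out100 <- notch(rec100)
  expect_lt(abs(max(abs(out100$samples[central, "TA_r"])) - 1), 0.05)
})

test_that("window_rms computes half-open-window RMS", {
  rec <- const_rec(rep(5, 200))
  expect_equal(window_rms(rec, 0.5, 1.5, "TA_r"), 5.0)

  # unit sinusoid over an integer number of periods
  x <- sin(2 * pi * 10 * (0:199) / 100)
  rec2 <- const_rec(x)
  expect_equal(window_rms(rec2, 0, 2, 1), 1 / sqrt(2), tolerance = 1e-6)

  # arbitrary 8-sample window vs hand-computed value
  v <- c(1.5, -2, 0, 3, 4, -1, 2.5, 0.5)
  rec3 <- const_rec(c(v, rep(0, 92)))
  expect_equal(window_rms(rec3, 0, 0.08, 1), sqrt(sum(v^2) / 8))

  # sign-flip invariance
  rec4 <- const_rec(-c(v, rep(0, 92)))
  expect_equal(window_rms(rec4, 0, 0.08, 1), window_rms(rec3, 0, 0.08, 1))

  expect_error(window_rms(rec, 1.0, 1.0, 1), "empty window")
  expect_error(window_rms(rec, 0, 5, 1), "outside")
})

test_that("estimate_baseline finds the quietest window", {
  rec0 <- const_rec(rep(0, 500))
  expect_equal(estimate_baseline(rec0, window_s = 3, step_s = 0.1)$baseline_rms,
               rep(0, 10))

  # noise with one silent 3-s gap: the gap must be found
  set.seed(22)
  x <- rnorm(2000, sd = 10)
  x[701:1000] <- 0  # 3 s at fs = 100
  rec <- const_rec(x)
  bp <- estimate_baseline(rec, step_s = 1 / 100)
  expect_equal(bp$baseline_rms[1], 0)
  expect_equal(bp$window_start_s[1], 7.0)

  # coarse stride within 2% of the exhaustive scan on a smooth envelope
  env <- 5 + 4 * sin(2 * pi * (0:1999) / 2000)
  set.seed(23)
  y <- env * rnorm(2000)
  recy <- const_rec(y)
  fine <- estimate_baseline(recy, step_s = 1 / 100)$baseline_rms[1]
  coarse <- estimate_baseline(recy, step_s = 0.1)$baseline_rms[1]
  expect_lt(abs(coarse - fine) / fine, 0.02)

  expect_error(estimate_baseline(const_rec(rep(1, 100))), "shorter")
})

test_that("baseline minimality: never exceeds any 3-s window RMS (stride-1 oracle)", {
  set.seed(24)
  for (i in 1:3) {
    x <- rnorm(800, sd = 3) * (1 + 0.5 * sin(2 * pi * (0:799) / 200))
    rec <- const_rec(x)
    bl <- estimate_baseline(rec, step_s = 1 / 100)$baseline_rms[1]
    n_win <- 300
    all_rms <- sapply(1:(800 - n_win + 1), function(s) {
      sqrt(mean(x[s:(s + n_win - 1)]^2))
    })
    expect_equal(bl, min(all_rms), tolerance = 1e-12)
    expect_true(all(bl <= all_rms + 1e-12))
  }
})

test_that("global artifact cutting shifts events and conserves other samples", {
  set.seed(25)
  x <- rnorm(1200)
  rec <- const_rec(x)
  ev <- one_task_events(start = 6, rep_s = 1, gap_s = 0.5)
  art <- artifact_table(data.frame(start_s = 1, end_s = 1.5, scope = "all",
                                   reason = "touch"))
  out <- cut_artifacts(rec, art, ev)
  expect_equal(nrow(out$recording$samples), 1200 - 50)
  expect_equal(as.data.frame(out$events)$start_s,
               as.data.frame(ev)$start_s - 0.5)
  # samples outside the cut are conserved in order
  expect_equal(out$recording$samples[, 1], x[-(101:150)])

  # no artifacts: identity
  out0 <- cut_artifacts(rec, artifact_table(NULL), ev)
  expect_equal(out0$recording$samples, rec$samples)
  expect_equal(as.data.frame(out0$events), as.data.frame(ev))
  expect_equal(nrow(out0$exclusions), 0)
})

test_that("channel-scoped artifacts exclude (channel, repetition) pairs", {
  set.seed(26)
  rec <- const_rec(rnorm(1200))
  ev <- one_task_events(start = 1, rep_s = 1, gap_s = 0.5)
  # inside repetition 2 (window [2.5, 3.5))
  art <- artifact_table(data.frame(start_s = 2.7, end_s = 2.9,
                                   scope = "GM_r", reason = "sensor touch"))
  out <- cut_artifacts(rec, art, ev)
  expect_equal(nrow(out$recording$samples), 1200)  # no time-axis cut
  expect_equal(out$exclusions,
               data.frame(task = "ankle_r", repetition = 2L, channel = "GM_r"))

  # the excluded repetition is dropped from that channel's average:
  # rep RMS 4, 6, 8 -> mean over reps {1, 3} = 6
  amp <- rep(0, 1200)
  amp[101:200] <- 4; amp[251:350] <- 6; amp[401:500] <- 8
  rec2 <- const_rec(amp)
  rv <- response_vector(rec2, ev, "ankle_r", baseline = flat_baseline(0),
                        exclusions = out$exclusions)
  expect_equal(unname(rv$values["GM_r"]), (4 + 8) / 2)
  expect_equal(unname(rv$values["TA_r"]), (4 + 6 + 8) / 3)
  expect_equal(unname(rv$n_reps_used["GM_r"]), 2L)
})

test_that("an artifact covering a whole repetition on all channels errors", {
  rec <- const_rec(rnorm(1200))
  ev <- one_task_events(start = 1, rep_s = 1, gap_s = 0.5)
  art <- artifact_table(data.frame(start_s = 2.4, end_s = 3.6, scope = "all",
                                   reason = "seat contact"))
  expect_error(cut_artifacts(rec, art, ev), "exclusion error.*repetition 2")
})
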