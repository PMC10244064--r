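fs <- 256

test_that("delta band power of a pure 2 Hz tone equals A^2/2", {
  t <- (0:(fs * 120 - 1)) / fs
  amp <- 50
  x <- amp * sin(2 * pi * 2 * t)
  rec <- eeg_recording(rbind(x, x), c("F3-C3", "F4-C4"), fs,
                       sides = c("left", "right"))
  seg <- quiet_segments(rec, stage_hyp("N2", 120), "N2")
  dp <- compute_delta_power(rec, seg)
  expect_lt(abs(dp$channel[["F3-C3"]] - amp^2 / 2) / (amp^2 / 2), 0.05)
  expect_equal(dp$left, dp$right)
})

test_that("out-of-band tones leave almost no delta power", {
  t <- (0:(fs * 60 - 1)) / fs
  x <- 40 * sin(2 * pi * 10 * t)
  rec <- eeg_recording(rbind(x), "F3-C3", fs, sides = "left")
  seg <- quiet_segments(rec, stage_hyp("N2", 60), "N2")
  dp <- compute_delta_power(rec, seg)
  total <- 40^2 / 2
  expect_lt(dp$channel[[1]], 0.01 * total)
})

test_that("white noise delta power matches the flat-spectrum expectation", {
  set.seed(77)
  sigma <- 12
  x <- rnorm(fs * 600, 0, sigma)
  rec <- eeg_recording(rbind(x), "F3-C3", fs, sides = "left")
  seg <- quiet_segments(rec, stage_hyp("N3", 600), "N3")
  dp <- compute_delta_power(rec, seg)
  expected <- sigma^2 * 3.5 / (fs / 2)
  expect_lt(abs(dp$channel[[1]] - expected) / expected, 0.1)
})

test_that("Welch windows never span a segment gap", {
  t <- (0:(fs * 60 - 1)) / fs
  x <- 30 * sin(2 * pi * 2 * t)
  rec <- eeg_recording(rbind(x), "F3-C3", fs, sides = "left")
  hyp <- hypnogram(c("N2", "W", "N2"), c(0, 20, 30), c(20, 10, 30))
  seg <- quiet_segments(rec, hyp, "N2")
  dp <- compute_delta_power(rec, seg)
  expect_lt(abs(dp$channel[[1]] - 450) / 450, 0.05)
  # a segment shorter than one window is an error when it is the only one
  seg1 <- quiet_segments(rec, hypnogram("N2", 0, 2), "N2")
  expect_error(compute_delta_power(rec, seg1), "Welch window")
})

test_that("an injected half-sine is detected with oracle-matched bounds", {
  x <- numeric(fs * 120)
  tt <- seq(0, 0.5, by = 1 / fs)
  x[(60 * fs):(60 * fs + length(tt) - 1)] <- -80 * sin(pi * tt / 0.5)
  rec <- make_flat_recording("a", 120, fs)
  seg <- quiet_segments(rec, stage_hyp("N2", 120), "N2")
  ev <- detect_slow_waves(x, x, fs, seg, channel = "F3-C3")
  expect_equal(nrow(ev), 1L)
  # filtered trough sits at the injected minimum
  expect_lt(abs(ev$trough_s - (60 * fs - 1 + 64) / fs), 2 / fs)
  expect_gt(ev$amplitude_uV, 0.6 * 80)
  expect_lt(ev$amplitude_uV, 1.05 * 80)
  expect_gt(ev$duration_s, 0.3)
  expect_lt(ev$duration_s, 0.6)
  expect_equal(ev$slope_uV_s, ev$amplitude_uV / ev$time_to_trough_s)
  # independent zero-crossing oracle reproduces the boundaries exactly
  yb <- bandpass_filter(x, fs, c(0.5, 4))
  orc <- oracle_negative_half_waves(yb, fs)
  orc <- orc[-yb[apply(orc, 1, function(r) {
    sp <- r[1]:r[2]; sp[which.min(yb[sp])]
  })] > 1e-9 * max(abs(yb)), , drop = FALSE]
  expect_equal(nrow(orc), 1L)
  expect_equal(ev$onset_s, unname((orc[1, "onset"] - 1) / fs))
  expect_equal(ev$offset_s, unname(orc[1, "offset"] / fs))
})

test_that("the duration criterion gates events on the filtered trace", {
  # in-band sinusoids pass the filter with their half-wave durations intact:
  # 1.25 Hz -> 0.4 s half-waves (kept); 2.2 Hz -> 0.227 s (too short);
  # 0.45 Hz -> 1.11 s (too long)
  t <- (0:(fs * 60 - 1)) / fs
  rec <- make_flat_recording("a", 60, fs)
  # keep the scored window away from the trace edges so that filter
  # start-up transients cannot masquerade as events
  seg <- quiet_segments(rec, hypnogram("N2", 2, 56), "N2")
  for (case in list(c(freq = 1.25, expected = 1),
                    c(freq = 2.2, expected = 0),
                    c(freq = 0.45, expected = 0))) {
    x <- 60 * sin(2 * pi * case[["freq"]] * t)
    ev <- detect_slow_waves(x, x, fs, seg)
    if (case[["expected"]] == 1) expect_gt(nrow(ev), 40)
    else expect_equal(nrow(ev), 0L)
  }
  # a short injected half-sine (0.15 s) is rejected
  x <- numeric(fs * 60)
  tt <- seq(0, 0.15, by = 1 / fs)
  x[(30 * fs):(30 * fs + length(tt) - 1)] <- -80 * sin(pi * tt / 0.15)
  expect_equal(nrow(detect_slow_waves(x, x, fs, seg)), 0L)
})

test_that("the average-reference cross-check rejects sign-inverted events", {
  x <- numeric(fs * 60)
  tt <- seq(0, 0.5, by = 1 / fs)
  x[(30 * fs):(30 * fs + length(tt) - 1)] <- -80 * sin(pi * tt / 0.5)
  rec <- make_flat_recording("a", 60, fs)
  seg <- quiet_segments(rec, stage_hyp("N2", 60), "N2")
  expect_equal(nrow(detect_slow_waves(x, x, fs, seg)), 1L)
  expect_equal(nrow(detect_slow_waves(x, -x, fs, seg)), 0L)
})

test_that("events outside scored segments are dropped", {
  x <- numeric(fs * 120)
  tt <- seq(0, 0.5, by = 1 / fs)
  for (at in c(30, 90))
    x[(at * fs):(at * fs + length(tt) - 1)] <- -80 * sin(pi * tt / 0.5)
  rec <- make_flat_recording("a", 120, fs)
  seg <- quiet_segments(rec, hypnogram(c("N2", "W"), c(0, 60), c(60, 60)),
                        "N2")
  ev <- detect_slow_waves(x, x, fs, seg)
  expect_equal(nrow(ev), 1L)
  expect_lt(ev$trough_s, 60)
})

test_that("detection boundaries are amplitude-scale equivariant", {
  set.seed(31)
  x <- pink_noise(fs * 90, fs, 1, 12)
  rec <- make_flat_recording("a", 90, fs)
  seg <- quiet_segments(rec, stage_hyp("N3", 90), "N3")
  e1 <- detect_slow_waves(x, x, fs, seg)
  # powers of two commute with floating-point rounding, so the scaled
  # detection run is bit-comparable
  e4 <- detect_slow_waves(4 * x, 4 * x, fs, seg)
  expect_gt(nrow(e1), 10)
  expect_equal(e1$onset_s, e4$onset_s)
  expect_equal(e1$offset_s, e4$offset_s)
  expect_equal(4 * e1$amplitude_uV, e4$amplitude_uV)
  expect_equal(4 * e1$slope_uV_s, e4$slope_uV_s)
})

test_that("every detected event satisfies the type invariants", {
  set.seed(13)
  for (rep in 1:3) {
    x <- pink_noise(fs * 60, fs, runif(1, 0.5, 1.5), runif(1, 5, 25))
    rec <- make_flat_recording("a", 60, fs)
    seg <- quiet_segments(rec, stage_hyp("N2", 60), "N2")
    ev <- detect_slow_waves(x, x, fs, seg)
    expect_true(all(ev$duration_s >= 0.25 & ev$duration_s <= 1))
    expect_true(all(ev$onset_s < ev$trough_s | ev$trough_s == ev$onset_s))
    expect_true(all(ev$trough_s < ev$offset_s))
    expect_true(all(ev$amplitude_uV > 0))
    expect_true(all(ev$slope_uV_s > 0))
  }
})

test_that("slow-wave summaries compute density and per-event features", {
  rec <- make_flat_recording("a", 1200, fs)
  seg <- quiet_segments(rec, stage_hyp("N2", 1200), "N2")
  ev <- data.frame(channel = rep("F3-C3", 30), onset_s = 1:30,
                   offset_s = 1:30 + 0.5, trough_s = 1:30 + 0.25,
                   amplitude_uV = 80, duration_s = 0.5,
                   time_to_trough_s = 0.4,
                   slope_uV_s = 80 / 0.4)
  s <- summarize_slow_waves(ev, seg, channels = c("F3-C3", "F7-T7"),
                            sides = c("left", "left"))
  expect_equal(s$channel$density_per_min[1], 30 / 20)
  expect_equal(s$channel$slope_uV_s[1], 200)
  # empty channel: density 0, undefined feature markers
  expect_equal(s$channel$density_per_min[2], 0)
  expect_true(is.na(s$channel$amplitude_uV[2]))
  # hemisphere average over both channels
  expect_equal(s$hemisphere$density_per_min[1], 0.75)
})
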