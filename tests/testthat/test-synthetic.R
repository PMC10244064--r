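short_sched <- default_schedule(8, 4)
red <- default_montage(reduced = TRUE)

test_that("simulation is bit-for-bit reproducible under a fixed seed", {
  sp <- patient_spec("P1", "left", li = c(sp_density = -0.1),
                     schedule = short_sched, montage = red, seed = 33)
  n1 <- simulate_night(sp, 1)
  n2 <- simulate_night(sp, 1)
  expect_identical(n1$recording$signal, n2$recording$signal)
  expect_identical(n1$events, n2$events)
  # different night index gives a different realization
  n3 <- simulate_night(sp, 2)
  expect_false(identical(n1$recording$signal, n3$recording$signal))
})

test_that("ground-truth LIs equal the generative parameter ratios exactly", {
  li <- c(delta_power = 0.08, sw_density = 0.2, sw_amplitude = -0.1,
          sp_density = -0.07, sp_locking = 0.15, ied_rate = 0.4)
  sp <- patient_spec("P1", "left", li = li, schedule = short_sched,
                     montage = red, seed = 1)
  tr <- truth_features(sp)
  for (f in names(li))
    expect_equal(tr$li[tr$feature == f], unname(li[f]), tolerance = 1e-9)
  expect_equal(tr$li, lateralization_index(tr$value_left, tr$value_right),
               tolerance = 1e-12)
})

test_that("mirroring a patient spec negates every ground-truth LI", {
  li <- c(delta_power = 0.08, sw_density = 0.2, sw_amplitude = -0.1,
          sw_duration = 0.05, sp_density = -0.07, sp_amplitude = 0.12,
          sp_duration = -0.02, sp_locking = 0.15, ied_rate = 0.4)
  sp <- patient_spec("P1", "left", li = li, schedule = short_sched,
                     montage = red, seed = 2)
  mir <- mirror_patient_spec(sp)
  expect_equal(mir$epileptic_side, "right")
  t1 <- truth_features(sp)
  t2 <- truth_features(mir)
  expect_equal(t2$li, -t1$li, tolerance = 1e-12)
  expect_equal(t2$value_left, t1$value_right)
})

test_that("zero event rates give pure noise and no detections", {
  sp <- patient_spec("P1", "left", sw_rate = 0, sp_rate = 0, ied_rate = 0,
                     itc_base = 0, schedule = short_sched, montage = red,
                     seed = 3)
  nt <- simulate_night(sp, 1)
  expect_null(nt$events$slow_waves)
  expect_null(nt$events$spindles)
  rec <- nt$recording
  fs <- rec$sampling_rate
  n2 <- quiet_segments(rec, nt$hypnogram, "N2")
  tr <- rec$signal["C3", ] - rec$signal["FT9", ]
  sp_ev <- detect_spindles(tr, fs, n2)
  # threshold crossings on pure noise exist, but no coherent bursts of
  # spindle scale: all "events" have small amplitude
  if (nrow(sp_ev) > 0) {
    f <- spindle_features(sp_ev, tr, fs, n2)
    expect_lt(f$amplitude_uV, 20)
  }
  # slow waves with an amplitude floor above the noise ceiling: none
  nrem <- combine_segments(n2, quiet_segments(rec, nt$hypnogram, "N3"))
  bip <- rec$signal["F3", ] - rec$signal["C3", ]
  ev <- detect_slow_waves(bip, rec$signal["F3", ], fs, nrem,
                          amplitude_floor = 35)
  expect_equal(nrow(ev), 0L)
})

test_that("slow-wave rate asymmetry is recovered in sign on every seed", {
  for (seed in 1:5) {
    sp <- patient_spec("P1", "left", li = c(sw_density = 1 / 3),
                       sw_rate = 6, schedule = short_sched, montage = red,
                       seed = seed)   # 8/min left vs 4/min right
    nt <- simulate_night(sp, 1)
    rec <- nt$recording
    fs <- rec$sampling_rate
    nrem <- combine_segments(quiet_segments(rec, nt$hypnogram, "N2"),
                             quiet_segments(rec, nt$hypnogram, "N3"))
    count <- function(pair) {
      bip <- rec$signal[pair[1], ] - rec$signal[pair[2], ]
      nrow(detect_slow_waves(bip, rec$signal[pair[1], ], fs, nrem,
                             amplitude_floor = 35))
    }
    left <- count(c("F3", "C3")) + count(c("F7", "T7"))
    right <- count(c("F4", "C4")) + count(c("F8", "T8"))
    expect_gt(lateralization_index(left, right), 0)
  }
})

test_that("coupling concentration drives downstream ITC monotonically", {
  for (seed in 1:3) {
    itcs <- vapply(c(0, 20), function(kap) {
      base <- if (kap == 0) 0 else 0.99
      sp <- patient_spec("P1", "left", itc_base = base,
                         sp_rate = 2.5, schedule = default_schedule(10, 2),
                         montage = red, seed = seed)
      nt <- simulate_night(sp, 1)
      rec <- nt$recording
      fs <- rec$sampling_rate
      tr <- rec$signal["C3", ] - rec$signal["FT9", ]
      n2 <- quiet_segments(rec, nt$hypnogram, "N2")
      ev <- detect_spindles(tr, fs, n2)
      itc(slow_osc_phase_at_troughs(tr, fs, ev))
    }, 0)
    expect_gt(itcs[2], itcs[1])
  }
})

test_that("a zero-asymmetry cohort centers every feature LI near zero", {
  cs <- cohort_spec(n_left = 150, n_right = 150,
                    li_median = setNames(rep(0, 9),
                                         names(cohort_spec()$li_median)),
                    seed = 44)
  co <- simulate_cohort(cs, signals = FALSE)
  tr <- co$truth
  for (f in unique(tr$feature)) {
    med <- median(tr$li[tr$feature == f])
    expect_lt(abs(med), 0.05)
  }
})

test_that("cohort truth medians match the programmed group profile", {
  cs <- cohort_spec(n_left = 500, n_right = 500, seed = 45)
  co <- simulate_cohort(cs, signals = FALSE)
  tr <- co$truth
  prof <- cs$li_median
  for (f in names(prof)) {
    tol <- if (f == "ied_rate") 0.08 else 0.03
    med_l <- median(tr$li[tr$feature == f & tr$group == "left"])
    med_r <- median(tr$li[tr$feature == f & tr$group == "right"])
    expect_lt(abs(med_l - prof[[f]]), tol)
    expect_lt(abs(med_r + prof[[f]]), tol)
  }
})

test_that("cohort simulation writes EDF, hypnogram and truth files", {
  dir <- file.path(tempdir(), "syncohort")
  cs <- cohort_spec(n_left = 1, n_right = 1, seed = 46,
                    schedule = default_schedule(4, 2), montage = red)
  co <- simulate_cohort(cs, nights = 1, signals = TRUE, dir = dir)
  expect_true(file.exists(file.path(dir, "P001_night1.edf")))
  expect_true(file.exists(file.path(dir, "P001_night1_hypnogram.csv")))
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  back <- read_recording(file.path(dir, "P001_night1.edf"), montage = red)
  orig <- co$patients[[1]]$nights[[1]]$recording
  expect_equal(back$channel_labels, orig$channel_labels)
  expect_lt(max(abs(back$signal - orig$signal)), 0.051)
  hyp <- read_hypnogram(file.path(dir, "P001_night1_hypnogram.csv"))
  expect_equal(as.data.frame(hyp),
               as.data.frame(co$patients[[1]]$nights[[1]]$hypnogram))
  unlink(dir, recursive = TRUE)
})

test_that("realized event rates stay close to nominal", {
  sp <- patient_spec("P1", "left", sw_rate = 6, sp_rate = 2,
                     schedule = default_schedule(10, 10), montage = red,
                     seed = 47)
  nt <- simulate_night(sp, 1)
  nrem_min <- 20
  sw_per_chan <- table(nt$events$slow_waves$channel)
  for (ch in names(sw_per_chan))
    expect_lt(abs(sw_per_chan[[ch]] / nrem_min - 6) / 6, 0.06)
  sp_per_chan <- table(nt$events$spindles$channel)
  for (ch in names(sp_per_chan))
    expect_lt(abs(sp_per_chan[[ch]] / 10 - 2) / 2, 0.06)
})

test_that("the truth-based feature matrix feeds the classifier", {
  co <- simulate_cohort(cohort_spec(20, 20, seed = 48), signals = FALSE)
  fm <- make_feature_matrix_from_truth(co, with_ied = TRUE)
  expect_equal(dim(fm$features), c(40L, 10L))
  expect_equal(sort(unique(fm$labels)), c("left", "right"))
  # zero-asymmetry cohort: chance; strong single feature: separable
  cs0 <- cohort_spec(17, 17,
                     li_median = setNames(rep(0, 9),
                                          names(cohort_spec()$li_median)),
                     seed = 49)
  fm0 <- make_feature_matrix_from_truth(simulate_cohort(cs0,
                                                        signals = FALSE))
  r0 <- run_repeated_cv(fm0$features, fm0$labels, n_iter = 150, seed = 50)
  expect_lt(abs(r0$mean_accuracy - 0.5), 0.06)
  li_strong <- c(delta_power = 0, sw_density = 0, sw_amplitude = 0,
                 sw_duration = 0, sp_density = -0.6, sp_amplitude = 0,
                 sp_duration = 0, sp_locking = 0, ied_rate = 0)
  sd_small <- setNames(rep(0.05, 9), names(li_strong))
  cs1 <- cohort_spec(17, 17, li_median = li_strong, li_sd = sd_small,
                     seed = 51)
  fm1 <- make_feature_matrix_from_truth(simulate_cohort(cs1,
                                                        signals = FALSE))
  r1 <- run_repeated_cv(fm1$features, fm1$labels, n_iter = 50, seed = 52)
  expect_gt(r1$mean_accuracy, 0.95)
})

test_that("von Mises sampling hits its analytic resultant length", {
  set.seed(53)
  for (kap in c(0.5, 2, 8)) {
    th <- rvonmises(4000, pi, kap)
    expect_true(all(th > -pi & th <= pi))
    r_hat <- itc(th)
    r_true <- besselI(kap, 1, TRUE) / besselI(kap, 0, TRUE)
    expect_lt(abs(r_hat - r_true), 0.03)
    # mean direction pi
    mu_hat <- Arg(mean(exp(1i * th)))
    expect_lt(abs(abs(mu_hat) - pi), 0.1)
  }
  expect_lt(itc(rvonmises(4000, 0, 0)), 0.05)
})

test_that("pink noise matches its target variance and spectral slope", {
  set.seed(54)
  fs <- 256
  x <- pink_noise(fs * 240, fs, beta = 1, sd = 12)
  expect_lt(abs(sd(x) - 12) / 12, 0.1)
  p <- welch_psd(x, fs, window_s = 8)
  sel1 <- p$freq >= 1 & p$freq < 2
  sel2 <- p$freq >= 8 & p$freq < 16
  # 1/f: power density ratio between octaves ~ centre-frequency ratio
  ratio <- mean(p$psd[sel1]) / mean(p$psd[sel2])
  expect_gt(ratio, 4)
  expect_lt(ratio, 13)
  # band gain raises in-band power by its square
  y0 <- pink_noise(fs * 240, fs, 1, 12, band_gain = 1)
  set.seed(55)
  y2 <- pink_noise(fs * 240, fs, 1, 12, band_gain = 2)
  rec0 <- eeg_recording(rbind(y0), "a", fs, sides = "left")
  rec2 <- eeg_recording(rbind(y2), "a", fs, sides = "left")
  seg <- quiet_segments(rec0, stage_hyp("N2", 240), "N2")
  b0 <- compute_delta_power(rec0, seg)$channel[[1]]
  b2 <- compute_delta_power(rec2, seg)$channel[[1]]
  expect_gt(b2 / b0, 2.5)
})
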