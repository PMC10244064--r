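# Synthetic sleep-EEG generator with known ground truth: 1/f background,
# injected negative half-wave slow waves, Hann-windowed 13 Hz spindle bursts
# (optionally phase-locked to the delta band), IED-like biphasic transients,
# and configurable left/right asymmetry of every feature.

#' von Mises random deviates (Best-Fisher rejection sampler)
#' @param n number of draws
#' @param mu mean direction (radians)
#' @param kappa concentration (>= 0); 0 gives the uniform circle
#' @return phases in (-pi, pi]
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa < 1e-8) {
    th <- stats::runif(n, -pi, pi)
  } else {
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    th <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        u <- stats::runif(3)
        z <- cos(pi * u[1])
        f <- (1 + r * z) / (r + z)
        cc <- kappa * (r - f)
        if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
          th[i] <- sign(u[3] - 0.5) * acos(f)
          break
        }
      }
    }
  }
  out <- (th + mu + pi) %% (2 * pi) - pi
  out[out <= -pi] <- pi
  out
}

# mean resultant length of the von Mises distribution, A(kappa) = I1/I0
.vm_resultant <- function(kappa) {
  if (kappa == 0) return(0)
  besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
}

# inverse of .vm_resultant: concentration giving a target resultant length
.vm_kappa_for <- function(r) {
  if (r <= 0) return(0)
  if (r >= 0.999) r <- 0.999
  stats::uniroot(function(k) .vm_resultant(k) - r, c(1e-8, 2000))$root
}

#' 1/f^beta Gaussian background noise
#'
#' White Gaussian noise spectrally shaped to amplitude ~ f^(-beta/2)
#' (power ~ 1/f^beta), rescaled to the requested standard deviation. An
#' optional multiplicative gain is applied to the amplitudes inside
#' \code{gain_band} before rescaling, so the in-band/out-of-band power ratio
#' (not the total normalization) carries the gain.
#'
#' @param n samples
#' @param sampling_rate Hz
#' @param beta spectral exponent in [0, 2]
#' @param sd target standard deviation (uV)
#' @param band_gain amplitude gain applied within \code{gain_band}
#' @param gain_band frequency band for \code{band_gain} (Hz)
#' @return numeric vector of length \code{n}
#' @export
pink_noise <- function(n, sampling_rate, beta = 1, sd = 15, band_gain = 1,
                       gain_band = c(0.5, 4)) {
  if (beta < 0 || beta > 2) stop("beta must be in [0, 2]")
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) * sampling_rate / n
  f <- pmin(f, sampling_rate - f)          # two-sided frequency axis
  amp <- ifelse(f > 0, f^(-beta / 2), 0)
  base <- Re(stats::fft(X * amp, inverse = TRUE) / n)
  norm <- stats::sd(base)
  if (band_gain != 1) {
    amp[f >= gain_band[1] & f <= gain_band[2]] <-
      amp[f >= gain_band[1] & f <= gain_band[2]] * band_gain
    shaped <- Re(stats::fft(X * amp, inverse = TRUE) / n)
  } else shaped <- base
  shaped / norm * sd
}

# hemisphere of a 10-20 electrode: odd-numbered left, even-numbered right
electrode_side <- function(label) {
  num <- suppressWarnings(as.integer(gsub("[^0-9]", "", label)))
  ifelse(is.na(num), NA_character_,
         ifelse(num %% 2 == 1L, "left", "right"))
}

#' Default synthetic night schedule
#' @param n2_minutes,n3_minutes total minutes of N2 and N3 (split in two
#'   blocks each); defaults meet the >= 20 min inclusion rule
#' @return data.frame \code{stage}, \code{minutes}
#' @export
default_schedule <- function(n2_minutes = 22, n3_minutes = 22) {
  data.frame(
    stage = c("W", "N1", "N2", "N3", "N2", "N3"),
    minutes = c(1, 2, n2_minutes / 2, n3_minutes / 2,
                n2_minutes / 2, n3_minutes / 2),
    stringsAsFactors = FALSE)
}

#' Specification of one synthetic patient
#'
#' Per-feature left/right generative parameters are derived from base values
#' and a named vector of target lateralization indices \code{li}: a base
#' value B and index l give left = B(1 + l), right = B(1 - l), so the ground
#' truth LI equals l exactly. Delta power is lateralized through the in-band
#' amplitude gain sqrt(1 +/- l) (power gain 1 +/- l); spindle-slow
#' oscillation locking through von Mises concentrations solved so that the
#' expected ITC is A_base(1 +/- l). Slow-wave slope carries no parameter of
#' its own: it is implied by the amplitude and duration parameters
#' (slope = amplitude / half-duration).
#'
#' @param patient_id identifier
#' @param epileptic_side \code{"left"} or \code{"right"}
#' @param li named numeric vector of target LIs (sign convention:
#'   left minus right over sum); recognized names: \code{delta_power},
#'   \code{sw_density}, \code{sw_amplitude}, \code{sw_duration},
#'   \code{sp_density}, \code{sp_amplitude}, \code{sp_duration},
#'   \code{sp_locking}, \code{ied_rate}; missing entries default to 0
#' @param sw_rate slow waves per minute per detection channel (N2+N3)
#' @param sw_amplitude slow-wave amplitude scale (uV)
#' @param sw_duration_bounds uniform duration bounds (s)
#' @param sp_rate spindles per minute per spindle channel (N2)
#' @param sp_amplitude spindle burst peak amplitude (uV)
#' @param sp_duration_bounds uniform duration bounds (s)
#' @param itc_base expected locking (ITC) at zero asymmetry, in [0, 1)
#' @param ied_rate IED-like transients per minute per hemisphere
#' @param ied_amplitude IED peak amplitude (uV)
#' @param noise_sd background standard deviation (uV)
#' @param beta 1/f spectral exponent
#' @param sampling_rate Hz (default 256)
#' @param schedule night schedule (\code{\link{default_schedule}})
#' @param montage electrodes simulated (\code{\link{default_montage}})
#' @param spread fraction of each event's amplitude reaching the cathode
#'   electrode of its pair
#' @param seed per-patient seed
#' @return object of class \code{"patient_spec"}
#' @export
patient_spec <- function(patient_id, epileptic_side = "left",
                         li = numeric(0),
                         sw_rate = 5, sw_amplitude = 100,
                         sw_duration_bounds = c(0.35, 0.8),
                         sp_rate = 1.5, sp_amplitude = 30,
                         sp_duration_bounds = c(0.8, 1.6),
                         itc_base = 0.45, ied_rate = 1, ied_amplitude = 60,
                         noise_sd = 10, beta = 1, sampling_rate = 256,
                         schedule = default_schedule(),
                         montage = default_montage(), spread = 0.25,
                         seed = 1L) {
  stopifnot(epileptic_side %in% c("left", "right"),
            sw_rate >= 0, sp_rate >= 0, ied_rate >= 0,
            sw_amplitude > 0, sp_amplitude > 0,
            beta >= 0, beta <= 2, itc_base >= 0, itc_base < 1)
  li_names <- c("delta_power", "sw_density", "sw_amplitude", "sw_duration",
                "sp_density", "sp_amplitude", "sp_duration", "sp_locking",
                "ied_rate")
  l <- stats::setNames(numeric(length(li_names)), li_names)
  unknown <- setdiff(names(li), c(li_names, "sw_slope"))
  if (length(unknown)) stop("unknown li name(s): ",
                            paste(unknown, collapse = ", "))
  l[intersect(names(li), li_names)] <- li[intersect(names(li), li_names)]
  if (any(abs(l) >= 1)) stop("target LIs must lie in (-1, 1)")
  two <- function(base, nm) c(left = base * (1 + l[[nm]]),
                              right = base * (1 - l[[nm]]))
  itc_t <- two(itc_base, "sp_locking")
  params <- list(
    delta_gain = sqrt(c(left = 1 + l[["delta_power"]],
                        right = 1 - l[["delta_power"]])),
    sw_rate = two(sw_rate, "sw_density"),
    sw_amplitude = two(sw_amplitude, "sw_amplitude"),
    sw_duration = list(left = sw_duration_bounds * (1 + l[["sw_duration"]]),
                       right = sw_duration_bounds * (1 - l[["sw_duration"]])),
    sp_rate = two(sp_rate, "sp_density"),
    sp_amplitude = two(sp_amplitude, "sp_amplitude"),
    sp_duration = list(left = sp_duration_bounds * (1 + l[["sp_duration"]]),
                       right = sp_duration_bounds * (1 - l[["sp_duration"]])),
    itc_target = itc_t,
    kappa = c(left = .vm_kappa_for(itc_t[["left"]]),
              right = .vm_kappa_for(itc_t[["right"]])),
    ied_rate = two(ied_rate, "ied_rate"))
  structure(list(patient_id = patient_id, epileptic_side = epileptic_side,
                 li = l, params = params, noise_sd = noise_sd, beta = beta,
                 sampling_rate = sampling_rate, schedule = schedule,
                 montage = montage, spread = spread, seed = as.integer(seed),
                 ied_amplitude = ied_amplitude),
            class = "patient_spec")
}

#' Mirror a patient specification (swap left and right parameters)
#'
#' Every ground-truth lateralization index of the mirrored spec is exactly
#' the negation of the original's.
#'
#' @param spec a \code{\link{patient_spec}}
#' @return the mirrored \code{patient_spec}
#' @export
mirror_patient_spec <- function(spec) {
  sw <- function(v) {
    if (is.list(v)) v[c("left", "right")] <- v[c("right", "left")]
    else v[c("left", "right")] <- v[c("right", "left")]
    v
  }
  spec$params <- lapply(spec$params, sw)
  spec$li <- -spec$li
  spec$epileptic_side <- setdiff(c("left", "right"),
                                 spec$epileptic_side)[1]
  spec
}

#' Ground-truth feature table of a patient specification
#'
#' Left/right generative values and their exact LIs for the nine sleep
#' features plus the IED rate. Slow-wave slope is derived as
#' amplitude / (mean duration / 2); delta power as the squared in-band gain.
#'
#' @param spec a \code{\link{patient_spec}}
#' @return data.frame: \code{feature}, \code{value_left},
#'   \code{value_right}, \code{li}
#' @export
truth_features <- function(spec) {
  p <- spec$params
  mdur <- function(b) mean(b)
  rows <- rbind(
    data.frame(feature = "delta_power",
               value_left = p$delta_gain[["left"]]^2,
               value_right = p$delta_gain[["right"]]^2),
    data.frame(feature = "sw_density", value_left = p$sw_rate[["left"]],
               value_right = p$sw_rate[["right"]]),
    data.frame(feature = "sw_amplitude",
               value_left = p$sw_amplitude[["left"]],
               value_right = p$sw_amplitude[["right"]]),
    data.frame(feature = "sw_duration",
               value_left = mdur(p$sw_duration$left),
               value_right = mdur(p$sw_duration$right)),
    data.frame(feature = "sw_slope",
               value_left = p$sw_amplitude[["left"]] /
                 (mdur(p$sw_duration$left) / 2),
               value_right = p$sw_amplitude[["right"]] /
                 (mdur(p$sw_duration$right) / 2)),
    data.frame(feature = "sp_density", value_left = p$sp_rate[["left"]],
               value_right = p$sp_rate[["right"]]),
    data.frame(feature = "sp_amplitude",
               value_left = p$sp_amplitude[["left"]],
               value_right = p$sp_amplitude[["right"]]),
    data.frame(feature = "sp_duration",
               value_left = mdur(p$sp_duration$left),
               value_right = mdur(p$sp_duration$right)),
    data.frame(feature = "sp_locking",
               value_left = p$itc_target[["left"]],
               value_right = p$itc_target[["right"]]),
    data.frame(feature = "ied_rate", value_left = p$ied_rate[["left"]],
               value_right = p$ied_rate[["right"]]))
  rows$li <- lateralization_index(rows$value_left, rows$value_right)
  rows$li[is.na(rows$li)] <- 0
  rows
}

# non-overlapping event onset placement within segments (times in seconds);
# up to 100 redraw attempts per event
.place_events <- function(segments, n_events, durations, taken = NULL) {
  placed <- numeric(0)
  dur_placed <- numeric(0)
  seg_len <- segments$offset_s - segments$onset_s
  for (i in seq_len(n_events)) {
    ok <- FALSE
    for (attempt in 1:100) {
      s <- sample.int(nrow(segments), 1L, prob = seg_len)
      if (seg_len[s] <= durations[i]) next
      onset <- stats::runif(1, segments$onset_s[s],
                            segments$offset_s[s] - durations[i])
      off <- onset + durations[i]
      busy <- FALSE
      if (length(placed))
        busy <- any(onset < placed + dur_placed & off > placed)
      if (!is.null(taken) && nrow(taken))
        busy <- busy || any(onset < taken$offset_s & off > taken$onset_s)
      if (!busy) { ok <- TRUE; break }
    }
    if (ok) { placed <- c(placed, onset); dur_placed <- c(dur_placed,
                                                          durations[i]) }
  }
  if (!length(placed))
    return(data.frame(onset_s = numeric(), offset_s = numeric()))
  ord <- order(placed)
  data.frame(onset_s = placed[ord], offset_s = (placed + dur_placed)[ord])
}

#' Simulate one synthetic night
#'
#' Per electrode: 1/f^beta Gaussian background with the hemisphere's delta
#' gain; slow waves injected as negative half-sines at the anodes of the
#' slow-wave detection pairs (a fraction \code{spread} reaches the cathode);
#' spindles as Hann-windowed 13 Hz bursts on the spindle channels during N2,
#' trough times placed where the bipolar trace's delta phase matches a von
#' Mises(pi, kappa) draw; IED-like 70 ms biphasic transients at the temporal
#' electrodes. All randomness derives from the spec seed and the night
#' index, so repeated calls are bit-for-bit identical.
#'
#' @param spec a \code{\link{patient_spec}}
#' @param night_idx night number (1-based)
#' @return list: \code{recording} (\code{eeg_recording}),
#'   \code{hypnogram}, \code{truth} (\code{\link{truth_features}}),
#'   \code{events} (list of injected event tables), \code{ied_counts}
#'   (named left/right), \code{night}
#' @export
simulate_night <- function(spec, night_idx = 1L) {
  fs <- spec$sampling_rate
  sched <- spec$schedule
  total_s <- sum(sched$minutes) * 60
  n <- round(total_s * fs)
  set.seed((as.numeric(spec$seed) * 1009 + night_idx * 7919) %% 2147483587)

  onset <- cumsum(c(0, sched$minutes * 60))[seq_len(nrow(sched))]
  hyp <- hypnogram(sched$stage, onset, sched$minutes * 60)
  stage_iv <- function(stages) {
    sel <- hyp[hyp$stage %in% stages, ]
    data.frame(onset_s = sel$onset_s,
               offset_s = sel$onset_s + sel$duration_s)
  }
  nrem <- stage_iv(c("N2", "N3"))
  n2 <- stage_iv("N2")
  if (!nrow(nrem)) stop("schedule contains no NREM sleep")

  electrodes <- montage_electrodes(spec$montage)
  sides <- electrode_side(electrodes)
  sig <- matrix(0, length(electrodes), n,
                dimnames = list(electrodes, NULL))
  for (i in seq_along(electrodes))
    sig[i, ] <- pink_noise(n, fs, spec$beta, spec$noise_sd,
                           band_gain = spec$params$delta_gain[[sides[i]]])

  p <- spec$params
  add_wave <- function(elec, t0, wave, frac = 1) {
    a <- round(t0 * fs) + 1L
    b <- a + length(wave) - 1L
    if (a < 1L || b > n) return(invisible(NULL))
    sig[elec, a:b] <<- sig[elec, a:b] + frac * wave
  }

  # --- slow waves at the detection-pair anodes -------------------------
  sw_pairs <- list(left = list(c("F3", "C3"), c("F7", "T7")),
                   right = list(c("F4", "C4"), c("F8", "T8")))
  sw_events <- list()
  for (side in c("left", "right")) {
    for (pair in sw_pairs[[side]]) {
      if (!all(pair %in% electrodes)) next
      n_ev <- round(p$sw_rate[[side]] *
                      sum(nrem$offset_s - nrem$onset_s) / 60)
      if (n_ev < 1L) next
      durs <- stats::runif(n_ev, p$sw_duration[[side]][1],
                           p$sw_duration[[side]][2])
      amps <- p$sw_amplitude[[side]] * stats::runif(n_ev, 0.9, 1.1)
      ev <- .place_events(nrem, n_ev, durs)
      for (j in seq_len(nrow(ev))) {
        d <- ev$offset_s[j] - ev$onset_s[j]
        tt <- seq(0, d, by = 1 / fs)
        wave <- -amps[j] * sin(pi * tt / d)
        add_wave(pair[1], ev$onset_s[j], wave)
        add_wave(pair[2], ev$onset_s[j], wave, frac = spec$spread)
      }
      if (nrow(ev)) {
        ev$channel <- paste(pair, collapse = "-")
        ev$side <- side
        sw_events[[length(sw_events) + 1L]] <- ev
      }
    }
  }

  # --- spindles on the spindle channels (N2 only) ----------------------
  sp_pairs <- list(left = c("C3", "FT9"), right = c("C4", "FT10"))
  sp_events <- list()
  for (side in c("left", "right")) {
    pair <- sp_pairs[[side]]
    if (!all(pair %in% electrodes) || !nrow(n2)) next
    n_ev <- round(p$sp_rate[[side]] * sum(n2$offset_s - n2$onset_s) / 60)
    if (n_ev < 1L) next
    # delta phase of the bipolar spindle trace (background + slow waves)
    bip <- sig[pair[1], ] - sig[pair[2], ]
    phase <- instantaneous_phase(bandpass_filter(bip, fs, c(0.5, 4)))
    durs <- stats::runif(n_ev, p$sp_duration[[side]][1],
                         p$sp_duration[[side]][2])
    amps <- p$sp_amplitude[[side]] * stats::runif(n_ev, 0.9, 1.1)
    targets <- rvonmises(n_ev, pi, p$kappa[[side]])
    ev <- .place_events(n2, n_ev, durs)
    troughs <- numeric(nrow(ev))
    for (j in seq_len(nrow(ev))) {
      d <- ev$offset_s[j] - ev$onset_s[j]
      # search +/- 0.4 s around the nominal trough for the target phase
      tc <- ev$onset_s[j] + d / 2
      a <- max(1L, round((tc - 0.4) * fs))
      b <- min(n, round((tc + 0.4) * fs))
      win <- a:b
      dist <- abs(Arg(exp(1i * (phase[win] - targets[j]))))
      ti <- win[which.min(dist)]
      troughs[j] <- (ti - 1L) / fs
      tt <- seq(0, d, by = 1 / fs)
      # Gaussian waxing-waning envelope: the centre trough is the deepest
      env <- exp(-((tt - d / 2)^2) / (2 * (d / 5)^2))
      # carrier phased so the center sample is the maximal trough
      carrier <- cos(2 * pi * 13 * (tt - d / 2) + pi)
      wave <- amps[j] * env * carrier
      # deepen the central trough by a fixed absolute margin (one carrier
      # cycle wide) so the maximal-trough time stays identifiable under
      # noise independently of the burst's amplitude scale
      cyc <- round(fs / 13)
      ci <- which.min(abs(tt - d / 2))
      lo <- max(1L, ci - cyc %/% 2L); hi <- min(length(tt), ci + cyc %/% 2L)
      bump <- cos(pi * (lo:hi - ci) / (cyc / 2))  # 1 at centre, 0 at edges
      wave[lo:hi] <- wave[lo:hi] - 6 * pmax(bump, 0)
      t0 <- troughs[j] - d / 2
      add_wave(pair[1], t0, wave)
      add_wave(pair[2], t0, wave, frac = spec$spread)
    }
    if (nrow(ev)) {
      ev$trough_s <- troughs
      ev$channel <- paste(pair, collapse = "-")
      ev$side <- side
      sp_events[[length(sp_events) + 1L]] <- ev
    }
  }

  # --- IED-like transients at the temporal electrodes ------------------
  ied_elec <- list(left = "T7", right = "T8")
  ied_counts <- c(left = 0, right = 0)
  for (side in c("left", "right")) {
    el <- ied_elec[[side]]
    if (!el %in% electrodes) el <- if (side == "left") "F7" else "F8"
    if (!el %in% electrodes) next
    n_ev <- round(p$ied_rate[[side]] *
                    sum(nrem$offset_s - nrem$onset_s) / 60)
    if (n_ev < 1L) next
    ev <- .place_events(nrem, n_ev, rep(0.07, n_ev))
    tt <- seq(0, 0.07, by = 1 / fs)
    wave <- -spec$ied_amplitude * sin(2 * pi * tt / 0.07)
    for (j in seq_len(nrow(ev))) add_wave(el, ev$onset_s[j], wave)
    ied_counts[[side]] <- nrow(ev)
  }

  rec <- eeg_recording(sig, electrodes, fs)
  list(recording = rec, hypnogram = hyp, truth = truth_features(spec),
       events = list(slow_waves = if (length(sw_events))
         do.call(rbind, sw_events) else NULL,
         spindles = if (length(sp_events))
           do.call(rbind, sp_events) else NULL),
       ied_counts = ied_counts, night = night_idx)
}

#' Specification of a synthetic two-group cohort
#'
#' Per-patient target LIs are drawn from group-level normal distributions
#' (median per feature, common spread), truncated to (-0.9, 0.9). The sign
#' convention of \code{li_median} is for left-focus patients (left minus
#' right); right-focus patients receive the negated medians. Defaults mirror
#' the reported effect directions: higher delta power, slow-wave amplitude
#' (hence slope) and spindle amplitude on the epileptic side; lower spindle
#' density on the epileptic side; strongly ipsilateral IEDs.
#'
#' @param n_left,n_right patients per focus group
#' @param li_median named vector of group-median LIs (left-focus convention)
#' @param li_sd named vector of per-feature spreads
#' @param seed master seed
#' @param ... further arguments passed to \code{\link{patient_spec}}
#'   (schedule, montage, rates, noise, ...)
#' @return object of class \code{"cohort_spec"}
#' @export
cohort_spec <- function(n_left = 34L, n_right = 35L,
                        li_median = c(delta_power = 0.05, sw_density = 0,
                                      sw_amplitude = 0.04, sw_duration = 0,
                                      sp_density = -0.07,
                                      sp_amplitude = 0.04, sp_duration = 0,
                                      sp_locking = 0, ied_rate = 0.30),
                        li_sd = c(delta_power = 0.12, sw_density = 0.12,
                                  sw_amplitude = 0.12, sw_duration = 0.12,
                                  sp_density = 0.12, sp_amplitude = 0.12,
                                  sp_duration = 0.12, sp_locking = 0.12,
                                  ied_rate = 0.35),
                        seed = 1L, ...) {
  stopifnot(n_left >= 1L, n_right >= 1L, all(abs(li_median) < 1))
  structure(list(n_left = as.integer(n_left),
                 n_right = as.integer(n_right),
                 li_median = li_median, li_sd = li_sd,
                 seed = as.integer(seed), patient_args = list(...)),
            class = "cohort_spec")
}

#' Simulate a synthetic cohort with ground truth
#'
#' Draws per-patient asymmetries around the group medians, builds one
#' \code{\link{patient_spec}} per patient, optionally synthesizes the signal
#' nights, and returns the ground-truth lateralization table. With
#' \code{dir} set, EDF recordings, hypnogram CSVs and a truth-table TSV are
#' written.
#'
#' @param cspec a \code{\link{cohort_spec}}
#' @param nights number of nights per patient (default 2)
#' @param signals synthesize raw signals (\code{TRUE}) or only the
#'   specifications and truth table (\code{FALSE}; fast path for
#'   statistics/classifier testing)
#' @param dir optional output directory for EDF + CSV + TSV files
#' @return list of class \code{"synthetic_cohort"}: \code{patients} (list of
#'   \code{spec} and, with signals, \code{nights}), \code{truth} (long
#'   data.frame: \code{patient_id}, \code{group}, \code{feature},
#'   \code{value_left}, \code{value_right}, \code{li}), \code{cohort_spec}
#' @export
simulate_cohort <- function(cspec, nights = 2L, signals = TRUE,
                            dir = NULL) {
  set.seed(cspec$seed)
  n_tot <- cspec$n_left + cspec$n_right
  groups <- rep(c("left", "right"), c(cspec$n_left, cspec$n_right))
  feat <- names(cspec$li_median)
  patient_seeds <- sample.int(2147483000L, n_tot)
  draw_li <- function(sign) {
    l <- stats::rnorm(length(feat), sign * cspec$li_median, cspec$li_sd)
    pmax(pmin(l, 0.9), -0.9)
  }
  lis <- t(vapply(groups, function(g) draw_li(if (g == "left") 1 else -1),
                  numeric(length(feat))))
  colnames(lis) <- feat
  patients <- vector("list", n_tot)
  truth <- list()
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(n_tot)) {
    id <- sprintf("P%03d", i)
    args <- c(list(patient_id = id, epileptic_side = groups[i],
                   li = lis[i, ], seed = patient_seeds[i]),
              cspec$patient_args)
    sp <- do.call(patient_spec, args)
    entry <- list(spec = sp)
    if (signals) {
      entry$nights <- lapply(seq_len(nights), function(k)
        simulate_night(sp, k))
      if (!is.null(dir)) {
        for (k in seq_len(nights)) {
          base <- file.path(dir, sprintf("%s_night%d", id, k))
          write_edf(entry$nights[[k]]$recording, paste0(base, ".edf"))
          write_hypnogram(entry$nights[[k]]$hypnogram,
                          paste0(base, "_hypnogram.csv"))
        }
      }
    }
    patients[[i]] <- entry
    tr <- truth_features(sp)
    tr$patient_id <- id
    tr$group <- groups[i]
    truth[[i]] <- tr
  }
  truth <- do.call(rbind, truth)
  truth <- truth[c("patient_id", "group", "feature", "value_left",
                   "value_right", "li")]
  if (!is.null(dir))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  structure(list(patients = patients, truth = truth, cohort_spec = cspec),
            class = "synthetic_cohort")
}

#' Classifier feature matrix from a cohort's ground truth
#'
#' Bypasses signal synthesis and processing: one row per patient, the
#' programmed per-patient LIs as features, focus side as the label. Intended
#' for fast statistical and classifier testing at cohort scale.
#'
#' @param cohort a \code{\link{simulate_cohort}} result
#' @param features feature names to keep (default the nine sleep features)
#' @param with_ied include the IED LI column
#' @return list: \code{features} (data.frame), \code{labels} (character)
#' @export
make_feature_matrix_from_truth <- function(cohort,
                                           features = sleep_features(),
                                           with_ied = FALSE) {
  tr <- cohort$truth
  if (with_ied) features <- union(features, "ied_rate")
  ids <- unique(tr$patient_id)
  m <- sapply(features, function(f)
    tr$li[match(paste(ids, f), paste(tr$patient_id, tr$feature))])
  m <- as.data.frame(m)
  # slow-wave slope is implied by amplitude and duration when not drawn
  if ("sw_slope" %in% features && all(is.na(m$sw_slope))) {
    la <- m$sw_amplitude; ld <- m$sw_duration
    m$sw_slope <- (la - ld) / (1 - la * ld)
  }
  labels <- tr$group[match(ids, tr$patient_id)]
  rownames(m) <- ids
  list(features = m, labels = labels)
}
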