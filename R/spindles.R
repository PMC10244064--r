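#' Default spindle-detector parameters
#'
#' An RMS amplitude-envelope detector in the Moelle family: the trace is
#' band-pass filtered 11-16 Hz, its root-mean-square envelope (0.2 s centered
#' window) is thresholded at the segment mean plus 1.5 standard deviations,
#' supra-threshold runs lasting 0.5-3 s are events, and events separated by
#' less than 0.5 s are merged. Two refinements make the duration criterion
#' refer to the burst itself rather than its smeared envelope run: event
#' boundaries come from the run shrunk by a quarter RMS window per side,
#' and the minimum-duration bound is checked against the envelope's width
#' around its peak at one third of the peak level, which estimates the
#' burst extent independently of where the threshold happens to sit (so a
#' 0.3 s burst is rejected at any SNR). The baseline statistics are
#' computed over the N2 envelope only.
#'
#' @param band detection band in Hz
#' @param rms_window_s RMS window (s)
#' @param threshold_sd threshold in envelope standard deviations above mean
#' @param min_dur_s,max_dur_s event duration bounds (s)
#' @param merge_gap_s events closer than this are merged (s)
#' @return named list of parameters
#' @export
spindle_params <- function(band = c(11, 16), rms_window_s = 0.2,
                           threshold_sd = 1.5, min_dur_s = 0.5,
                           max_dur_s = 3, merge_gap_s = 0.5) {
  list(band = band, rms_window_s = rms_window_s, threshold_sd = threshold_sd,
       min_dur_s = min_dur_s, max_dur_s = max_dur_s,
       merge_gap_s = merge_gap_s)
}

#' Detect sleep spindles during N2
#'
#' See \code{\link{spindle_params}} for the detection algorithm. Detection is
#' restricted to the supplied N2 segments; the threshold is computed from the
#' envelope over those segments only. The trough time of each event is the
#' minimum of the band-pass filtered signal within the event.
#'
#' @param trace numeric vector, one spindle channel (e.g. C3-FT9)
#' @param sampling_rate Hz
#' @param n2_segments \code{stage_segments} of stage N2 (a different stage is
#'   an error)
#' @param params \code{\link{spindle_params}} list
#' @param channel label stored on the events
#' @return data.frame of spindle events: \code{channel}, \code{onset_s},
#'   \code{offset_s}, \code{trough_s}, \code{duration_s}
#' @export
detect_spindles <- function(trace, sampling_rate, n2_segments,
                            params = spindle_params(),
                            channel = NA_character_) {
  stg <- attr(n2_segments, "stage")
  if (!is.null(stg) && !identical(stg, "N2"))
    stop("spindle detection requires N2 segments (got ", stg, ")")
  fs <- sampling_rate
  yf <- bandpass_filter(trace, fs, params$band)
  env <- rms_envelope(yf, fs, params$rms_window_s)
  idx <- .segment_index(n2_segments, fs, length(trace))
  if (!length(idx)) stop("N2 segments cover no samples")
  thr <- mean(env[idx]) + params$threshold_sd * stats::sd(env[idx])
  inseg <- logical(length(trace)); inseg[idx] <- TRUE
  runs <- .true_runs(env > thr & inseg)
  empty <- data.frame(channel = character(), onset_s = numeric(),
                      offset_s = numeric(), trough_s = numeric(),
                      duration_s = numeric())
  if (is.null(runs) || nrow(runs) == 0L) return(empty)
  # merge runs separated by less than merge_gap_s
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) for (i in 2L:nrow(runs)) {
    last <- nrow(merged)
    if ((runs[i, "start"] - merged[last, "end"]) / fs < params$merge_gap_s)
      merged[last, "end"] <- runs[i, "end"]
    else merged <- rbind(merged, runs[i, , drop = FALSE])
  }
  # the moving RMS window smears a burst's supra-threshold run outwards, and
  # how far depends on where the threshold sits relative to the burst's
  # envelope peak; event boundaries therefore come from the run shrunk by a
  # quarter window per side, while the MINIMUM-duration gate is applied to
  # the envelope's width around its peak at one third of the peak level,
  # which estimates the burst's own extent independently of the threshold
  # position (a 0.3 s burst is rejected at any SNR; the maximum-duration
  # gate stays on the run, where it catches sustained artifacts)
  shrink <- round(params$rms_window_s * fs / 4)
  on_i <- pmin(merged[, "start"] + shrink, merged[, "end"])
  off_i <- pmax(merged[, "end"] - shrink, merged[, "start"])
  dur <- (off_i - on_i + 1L) / fs
  core_w <- vapply(seq_len(nrow(merged)), function(i) {
    span <- merged[i, "start"]:merged[i, "end"]
    pk <- which.max(env[span])
    level <- max(thr, env[span][pk] / 3)
    above <- env[span] >= level
    a <- pk; while (a > 1L && above[a - 1L]) a <- a - 1L
    b <- pk; while (b < length(span) && above[b + 1L]) b <- b + 1L
    (b - a + 1L) / fs
  }, 0)
  keep <- core_w >= params$min_dur_s & dur <= params$max_dur_s
  if (!any(keep)) return(empty)
  merged <- merged[keep, , drop = FALSE]
  on_i <- on_i[keep]; off_i <- off_i[keep]
  trough_i <- vapply(seq_len(nrow(merged)), function(i) {
    span <- merged[i, "start"]:merged[i, "end"]
    span[which.min(yf[span])]
  }, 0L)
  data.frame(channel = channel,
             onset_s = (on_i - 1L) / fs,
             offset_s = off_i / fs,
             trough_s = pmin(pmax((trough_i - 1L) / fs, (on_i - 1L) / fs),
                             off_i / fs),
             duration_s = dur[keep],
             stringsAsFactors = FALSE)
}

#' Spindle density, amplitude and duration
#'
#' Density is events per minute of N2. Per-event amplitude is the
#' maximum-minus-minimum range of the 11-16 Hz filtered +/- 3 s epoch around
#' the event's maximal trough; epochs truncated by a recording edge are
#' flagged but still counted for density.
#'
#' @param events spindle event table (\code{\link{detect_spindles}})
#' @param trace the raw channel trace the events came from
#' @param sampling_rate Hz
#' @param n2_segments \code{stage_segments} of N2
#' @param band filter band for the amplitude epoch (default 11-16 Hz)
#' @param epoch_s half-width of the epoch in seconds (default 3)
#' @param central summary statistic (default median)
#' @return list: \code{density_per_min}, \code{amplitude_uV},
#'   \code{duration_s} (summaries), \code{per_event} (data.frame with
#'   \code{amplitude_uV} and \code{truncated}), \code{minutes}
#' @export
spindle_features <- function(events, trace, sampling_rate, n2_segments,
                             band = c(11, 16), epoch_s = 3,
                             central = stats::median) {
  minutes <- segment_minutes(n2_segments)
  if (minutes <= 0) stop("N2 segments cover zero minutes")
  fs <- sampling_rate
  if (nrow(events) == 0L)
    return(list(density_per_min = 0, amplitude_uV = NA_real_,
                duration_s = NA_real_,
                per_event = data.frame(amplitude_uV = numeric(),
                                       truncated = logical()),
                minutes = minutes))
  half <- round(epoch_s * fs)
  per <- lapply(seq_len(nrow(events)), function(i) {
    ti <- round(events$trough_s[i] * fs) + 1L
    a <- max(1L, ti - half); b <- min(length(trace), ti + half)
    epoch <- bandpass_filter(trace[a:b], fs, band)
    # range taken over the spindle itself (its extent within the epoch)
    ia <- max(1L, round(events$onset_s[i] * fs) + 1L - a + 1L)
    ib <- min(length(epoch), round(events$offset_s[i] * fs) - a + 1L)
    if (ib < ia) { ia <- 1L; ib <- length(epoch) }
    c(amp = max(epoch[ia:ib]) - min(epoch[ia:ib]),
      trunc = (ti - half < 1L) || (ti + half > length(trace)))
  })
  per <- do.call(rbind, per)
  list(density_per_min = nrow(events) / minutes,
       amplitude_uV = central(per[, "amp"]),
       duration_s = central(events$duration_s),
       per_event = data.frame(amplitude_uV = per[, "amp"],
                              truncated = as.logical(per[, "trunc"])),
       minutes = minutes)
}

#' Slow-oscillation phase at spindle troughs
#'
#' For each spindle, the +/- 3 s raw epoch around its maximal trough is
#' filtered 0.5-4 Hz and the instantaneous Hilbert phase is read at the
#' trough sample (cosine convention: 0 at a delta peak, +/- pi at a delta
#' trough). Epochs truncated to less than \code{min_epoch_s} are excluded and
#' counted.
#'
#' @param raw_trace raw (unfiltered) channel trace
#' @param sampling_rate Hz
#' @param events spindle event table (nonempty)
#' @param delta_band slow-oscillation band (default 0.5-4 Hz)
#' @param epoch_s epoch half-width (default 3 s)
#' @param min_epoch_s minimum usable epoch length in seconds (default 1)
#' @return list of class \code{"phase_set"}: \code{phases} (radians,
#'   (-pi, pi]), \code{n}, \code{n_excluded}
#' @export
slow_osc_phase_at_troughs <- function(raw_trace, sampling_rate, events,
                                      delta_band = c(0.5, 4), epoch_s = 3,
                                      min_epoch_s = 1) {
  if (nrow(events) == 0L) stop("no spindle events supplied")
  fs <- sampling_rate
  half <- round(epoch_s * fs)
  phases <- numeric(0); excl <- 0L
  for (i in seq_len(nrow(events))) {
    ti <- round(events$trough_s[i] * fs) + 1L
    a <- max(1L, ti - half); b <- min(length(raw_trace), ti + half)
    if ((b - a + 1L) / fs < min_epoch_s) { excl <- excl + 1L; next }
    epoch <- bandpass_filter(raw_trace[a:b], fs, delta_band)
    ph <- instantaneous_phase(epoch)
    phases <- c(phases, ph[ti - a + 1L])
  }
  structure(list(phases = phases, n = length(phases), n_excluded = excl),
            class = "phase_set")
}

#' Inter-trial coherence of a phase set
#'
#' The magnitude of the mean unit phase vector,
#' \eqn{ITC = \frac{1}{N}\,|\sum_{k=1}^{N} e^{i\varphi_k}|}: 1 under perfect
#' phase locking, approaching 0 for uniform phases. Amplitude never enters
#' the computation, so the measure is invariant to event amplitudes by
#' construction.
#'
#' @param phases a \code{phase_set} or numeric vector of phases in radians
#' @return coherence in [0, 1]; \code{NA} for an empty phase set (undefined,
#'   not zero)
#' @export
itc <- function(phases) {
  if (inherits(phases, "phase_set")) phases <- phases$phases
  if (length(phases) == 0L) return(NA_real_)
  Mod(mean(exp(1i * phases)))
}
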