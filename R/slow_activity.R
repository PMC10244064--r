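#' Delta-band power as a slow-oscillation proxy
#'
#' Welch spectral power in the 0.5-4 Hz band, computed per bipolar channel
#' over the scored NREM segments. Windows never span a gap: each segment is
#' windowed separately and periodograms are averaged with weights equal to
#' the number of windows each segment contributes. The per-hemisphere
#' aggregate is the arithmetic mean over that side's lateralized channels.
#'
#' @param traces bipolar \code{\link{eeg_recording}} (with \code{sides} tags)
#' @param segments a \code{\link{extract_segments}} result (typically N2+N3)
#' @param band frequency band in Hz (default \code{c(0.5, 4)})
#' @param window_s,overlap Welch parameters (default 4 s Hamming, 50\%)
#' @return list of class \code{"delta_power"}: \code{channel} (named vector of
#'   band powers, uV^2), \code{left}, \code{right} (hemisphere means),
#'   \code{minutes} used
#' @export
compute_delta_power <- function(traces, segments, band = c(0.5, 4),
                                window_s = 4, overlap = 0.5) {
  fs <- traces$sampling_rate
  if (band[2] >= fs / 2) stop("band exceeds Nyquist frequency")
  if (nrow(segments) == 0L) stop("no segments supplied")
  nwin <- round(window_s * fs)
  seg_idx <- lapply(seq_len(nrow(segments)), function(i)
    .segment_index(segments[i, , drop = FALSE], fs, ncol(traces$signal),
                   traces$start_time))
  seg_idx <- seg_idx[vapply(seg_idx, length, 0L) >= nwin]
  if (!length(seg_idx))
    stop("every segment is shorter than one Welch window")
  pow <- vapply(seq_len(nrow(traces$signal)), function(ch) {
    acc <- NULL; wts <- 0
    for (idx in seg_idx) {
      p <- welch_psd(traces$signal[ch, idx], fs, window_s, overlap)
      nw <- length(seq(1L, length(idx) - nwin + 1L,
                       by = max(1L, round(nwin * (1 - overlap)))))
      acc <- if (is.null(acc)) p$psd * nw else acc + p$psd * nw
      wts <- wts + nw
      freq <- p$freq
    }
    band_power(list(freq = freq, psd = acc / wts), band)
  }, 0)
  names(pow) <- traces$channel_labels
  sides <- traces$sides
  structure(list(channel = pow,
                 left = mean(pow[sides == "left"]),
                 right = mean(pow[sides == "right"]),
                 minutes = segment_minutes(segments)),
            class = "delta_power")
}

# negative half-waves of a filtered trace: spans between consecutive
# positive-to-negative and negative-to-positive zero crossings
.negative_half_waves <- function(y, fs, dur_range = NULL) {
  s <- sign(y)
  s[s == 0] <- 1
  d <- diff(s)
  p2n <- which(d < 0)        # last sample >= 0 before the negative span
  n2p <- which(d > 0)        # last negative sample of the span
  if (!length(p2n) || !length(n2p)) return(NULL)
  n2p <- n2p[n2p > p2n[1L]]
  if (!length(n2p)) return(NULL)
  on <- p2n[seq_along(n2p)]
  off <- n2p
  keep <- !is.na(on) & off > on
  on <- on[keep]; off <- off[keep]
  if (!length(on)) return(NULL)
  ev <- data.frame(onset = on + 1L, offset = off)
  ev$duration_s <- (ev$offset - ev$onset + 1L) / fs
  if (!is.null(dur_range))
    ev <- ev[ev$duration_s >= dur_range[1] & ev$duration_s <= dur_range[2], ,
             drop = FALSE]
  ev
}

#' Detect sleep slow waves on a bipolar trace
#'
#' Both the bipolar trace and the matching average-referenced trace are
#' band-pass filtered 0.5-4 Hz (zero-phase Butterworth). Negative half-waves
#' of the bipolar trace lasting between \code{dur_range[1]} and
#' \code{dur_range[2]} seconds (0.25-1 s by default) are candidate slow waves;
#' a candidate is retained only if the average-referenced trace also contains
#' a qualifying negative half-wave whose span covers the bipolar trough time,
#' and if the event lies entirely within the scored segments.
#'
#' @param bipolar_trace,avgref_trace numeric vectors, sample-aligned; the
#'   average-referenced trace is the anode electrode of the bipolar pair
#' @param sampling_rate Hz
#' @param segments \code{stage_segments} (N2+N3)
#' @param dur_range half-wave duration bounds in seconds
#' @param amplitude_floor optional minimum trough depth in uV (default 0: the
#'   detection criterion is duration only)
#' @param channel label stored on the events
#' @return data.frame of slow-wave events: \code{channel}, \code{onset_s},
#'   \code{offset_s}, \code{trough_s}, \code{amplitude_uV},
#'   \code{duration_s}, \code{time_to_trough_s}, \code{slope_uV_s}
#' @export
detect_slow_waves <- function(bipolar_trace, avgref_trace, sampling_rate,
                              segments, dur_range = c(0.25, 1),
                              amplitude_floor = 0, channel = NA_character_) {
  if (length(bipolar_trace) != length(avgref_trace))
    stop("bipolar and average-referenced traces must be sample-aligned")
  fs <- sampling_rate
  yb <- bandpass_filter(bipolar_trace, fs, c(0.5, 4))
  ya <- bandpass_filter(avgref_trace, fs, c(0.5, 4))
  ev <- .negative_half_waves(yb, fs, dur_range)
  empty <- data.frame(channel = character(), onset_s = numeric(),
                      offset_s = numeric(), trough_s = numeric(),
                      amplitude_uV = numeric(), duration_s = numeric(),
                      time_to_trough_s = numeric(), slope_uV_s = numeric())
  if (is.null(ev) || nrow(ev) == 0L) return(empty)
  av <- .negative_half_waves(ya, fs, dur_range)
  trough_i <- vapply(seq_len(nrow(ev)), function(i) {
    span <- ev$onset[i]:ev$offset[i]
    span[which.min(yb[span])]
  }, 0L)
  amp <- -yb[trough_i]
  # relative numerical floor: discards filter-ripple "events" on otherwise
  # flat traces while preserving amplitude-scale equivariance
  keep <- amp >= max(amplitude_floor, 1e-9 * max(abs(yb)))
  # cross-check: a qualifying avg-ref half-wave must cover the bipolar trough
  if (is.null(av) || nrow(av) == 0L) keep[] <- FALSE else
    keep <- keep & vapply(trough_i, function(ti)
      any(av$onset <= ti & av$offset >= ti), TRUE)
  # events entirely within scored segments
  onset_s <- (ev$onset - 1L) / fs
  offset_s <- ev$offset / fs
  inseg <- vapply(seq_len(nrow(ev)), function(i)
    any(segments$onset_s <= onset_s[i] & segments$offset_s >= offset_s[i]),
    TRUE)
  keep <- keep & inseg
  ev <- ev[keep, , drop = FALSE]
  if (nrow(ev) == 0L) return(empty)
  trough_i <- trough_i[keep]
  data.frame(channel = channel,
             onset_s = (ev$onset - 1L) / fs,
             offset_s = ev$offset / fs,
             trough_s = (trough_i - 1L) / fs,
             amplitude_uV = -yb[trough_i],
             duration_s = ev$duration_s,
             time_to_trough_s = (trough_i - ev$onset) / fs,
             slope_uV_s = -yb[trough_i] / ((trough_i - ev$onset) / fs),
             stringsAsFactors = FALSE)
}

#' Summarize slow-wave events per channel and hemisphere
#'
#' Density is events per minute of scored time. Amplitude, duration and slope
#' are summarized by \code{central} (median by default) per channel, then
#' averaged within each hemisphere. With no events the density is 0 and the
#' other features are \code{NA} (undefined, never silently zero).
#'
#' @param events slow-wave event table (\code{\link{detect_slow_waves}})
#' @param segments \code{stage_segments} used for detection
#' @param channels character vector of all detection channels (channels with
#'   zero events then still enter the summaries with density 0); defaults to
#'   the channels present in \code{events}
#' @param sides optional side tags (\code{"left"}/\code{"right"}) matching
#'   \code{channels}; enables the hemisphere summary
#' @param central summary statistic (default \code{stats::median})
#' @return list with \code{channel} (data.frame) and \code{hemisphere}
#'   (data.frame with one row per side, or \code{NULL})
#' @export
summarize_slow_waves <- function(events, segments,
                                 channels = unique(events$channel),
                                 sides = NULL, central = stats::median) {
  minutes <- segment_minutes(segments)
  if (minutes <= 0) stop("segments cover zero minutes")
  summarize_one <- function(e) {
    if (nrow(e) == 0L)
      return(c(density_per_min = 0, amplitude_uV = NA_real_,
               duration_s = NA_real_, slope_uV_s = NA_real_))
    c(density_per_min = nrow(e) / minutes,
      amplitude_uV = central(e$amplitude_uV),
      duration_s = central(e$duration_s),
      slope_uV_s = central(e$slope_uV_s))
  }
  per_chan <- do.call(rbind, lapply(channels, function(ch)
    summarize_one(events[events$channel == ch, , drop = FALSE])))
  channel_df <- data.frame(channel = channels, per_chan, row.names = NULL)
  hemi <- NULL
  if (!is.null(sides)) {
    hemi <- do.call(rbind, lapply(unique(sides), function(s)
      colMeans(channel_df[sides == s, -1, drop = FALSE], na.rm = FALSE)))
    hemi <- data.frame(side = unique(sides), hemi, row.names = NULL)
  }
  list(channel = channel_df, hemisphere = hemi, minutes = minutes)
}
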