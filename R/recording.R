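#' Construct an EEG recording object
#'
#' Container for a multichannel EEG signal: a channels x samples matrix in
#' microvolts, channel labels and a sampling rate.
#'
#' @param signal numeric matrix, channels x samples (microvolts)
#' @param channel_labels character vector, one per row of \code{signal}
#' @param sampling_rate sampling rate in Hz (> 0)
#' @param start_time offset of the first sample in seconds (default 0)
#' @param sides optional character vector tagging each channel
#'   \code{"left"}/\code{"right"} (set by \code{\link{derive_bipolar}})
#' @return object of class \code{"eeg_recording"}
#' @export
eeg_recording <- function(signal, channel_labels, sampling_rate,
                          start_time = 0, sides = NULL) {
  signal <- as.matrix(signal)
  stopifnot(is.numeric(sampling_rate), length(sampling_rate) == 1L,
            sampling_rate > 0)
  if (length(channel_labels) != nrow(signal))
    stop("channel_labels must have one entry per signal row")
  if (!is.null(sides) && length(sides) != nrow(signal))
    stop("sides must have one entry per channel")
  rownames(signal) <- channel_labels
  structure(list(signal = signal,
                 channel_labels = as.character(channel_labels),
                 sampling_rate = sampling_rate,
                 start_time = start_time,
                 sides = sides),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f min)\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate,
              ncol(x$signal) / x$sampling_rate / 60))
  cat("  channels:", paste(utils::head(x$channel_labels, 8), collapse = ", "),
      if (length(x$channel_labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' Number of seconds in a recording
#' @param rec an \code{eeg_recording}
#' @return recording duration in seconds
#' @export
recording_duration <- function(rec) ncol(rec$signal) / rec$sampling_rate

#' Derive a bipolar montage from a referential recording
#'
#' Each derived trace is anode minus cathode, sample-aligned; hemisphere tags
#' of the montage pairs are carried on the result.
#'
#' @param rec an \code{eeg_recording} with referential channels
#' @param montage a \code{\link{default_montage}}-style data.frame
#'   (\code{anode}, \code{cathode}, \code{side})
#' @return an \code{eeg_recording} with one channel per pair, labelled
#'   \code{"anode-cathode"}, and \code{sides} set
#' @export
derive_bipolar <- function(rec, montage = default_montage()) {
  need <- montage_electrodes(montage)
  missing <- setdiff(need, rec$channel_labels)
  if (length(missing))
    stop("recording lacks electrode(s) required by montage: ",
         paste(missing, collapse = ", "))
  ia <- match(montage$anode, rec$channel_labels)
  ic <- match(montage$cathode, rec$channel_labels)
  sig <- rec$signal[ia, , drop = FALSE] - rec$signal[ic, , drop = FALSE]
  eeg_recording(sig, paste0(montage$anode, "-", montage$cathode),
                rec$sampling_rate, rec$start_time, sides = montage$side)
}

#' Re-reference a recording to the common average
#'
#' Each trace becomes the original minus the mean over the configured
#' electrode set at each sample.
#'
#' @param rec an \code{eeg_recording}
#' @param electrodes labels entering the average (default: all channels of the
#'   recording). At least two are required.
#' @return an \code{eeg_recording} with the same channels, average-referenced
#' @export
derive_average_reference <- function(rec, electrodes = rec$channel_labels) {
  electrodes <- intersect(electrodes, rec$channel_labels)
  if (length(electrodes) < 2L)
    stop("average reference requires at least 2 electrodes")
  idx <- match(electrodes, rec$channel_labels)
  ref <- colMeans(rec$signal[idx, , drop = FALSE])
  sig <- sweep(rec$signal, 2L, ref, "-")
  eeg_recording(sig, rec$channel_labels, rec$sampling_rate, rec$start_time,
                sides = rec$sides)
}

#' Construct a hypnogram
#'
#' @param stage character vector of stage labels
#'   (\code{W, N1, N2, N3, REM, ART})
#' @param onset_s,duration_s numeric vectors, seconds from recording start;
#'   epochs must be non-overlapping with positive durations
#' @return data.frame of class \code{"hypnogram"}
#' @export
hypnogram <- function(stage, onset_s, duration_s) {
  stage <- as.character(stage)
  ok <- c("W", "N1", "N2", "N3", "REM", "ART")
  if (!all(stage %in% ok))
    stop("unknown stage label(s): ",
         paste(setdiff(stage, ok), collapse = ", "))
  if (any(duration_s <= 0)) stop("epoch durations must be > 0")
  h <- data.frame(stage = stage, onset_s = as.numeric(onset_s),
                  duration_s = as.numeric(duration_s),
                  stringsAsFactors = FALSE)
  h <- h[order(h$onset_s), , drop = FALSE]
  if (nrow(h) > 1L &&
      any(h$onset_s[-1L] < (h$onset_s + h$duration_s)[-nrow(h)] - 1e-9))
    stop("hypnogram epochs overlap")
  rownames(h) <- NULL
  class(h) <- c("hypnogram", "data.frame")
  h
}

#' Read / write a hypnogram CSV (columns stage,onset_s,duration_s)
#' @param path file path
#' @return \code{read_hypnogram}: a \code{\link{hypnogram}}
#' @export
read_hypnogram <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stage", "onset_s", "duration_s")
  if (!all(need %in% names(d)))
    stop("hypnogram CSV must have columns ", paste(need, collapse = ","))
  hypnogram(d$stage, d$onset_s, d$duration_s)
}

#' @rdname read_hypnogram
#' @param hyp a \code{\link{hypnogram}}
#' @export
write_hypnogram <- function(hyp, path) {
  utils::write.csv(as.data.frame(hyp)[c("stage", "onset_s", "duration_s")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an artifact mask CSV (columns onset_s,offset_s)
#' @param path file path
#' @return data.frame with \code{onset_s}, \code{offset_s}
#' @export
read_artifact_mask <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("onset_s", "offset_s") %in% names(d)))
    stop("artifact mask CSV must have columns onset_s,offset_s")
  d[c("onset_s", "offset_s")]
}

# subtract mask intervals from [on, off); all half-open seconds
.subtract_intervals <- function(iv, mask) {
  if (is.null(mask) || nrow(mask) == 0L || nrow(iv) == 0L) return(iv)
  out <- list()
  for (i in seq_len(nrow(iv))) {
    pieces <- data.frame(onset_s = iv$onset_s[i], offset_s = iv$offset_s[i])
    for (j in seq_len(nrow(mask))) {
      nxt <- list()
      for (k in seq_len(nrow(pieces))) {
        a <- pieces$onset_s[k]; b <- pieces$offset_s[k]
        m1 <- mask$onset_s[j]; m2 <- mask$offset_s[j]
        if (m2 <= a || m1 >= b) {           # no overlap
          nxt[[length(nxt) + 1L]] <- c(a, b)
        } else {
          if (m1 > a) nxt[[length(nxt) + 1L]] <- c(a, m1)
          if (m2 < b) nxt[[length(nxt) + 1L]] <- c(m2, b)
        }
      }
      pieces <- if (length(nxt))
        as.data.frame(do.call(rbind, nxt)) else
        data.frame(V1 = numeric(), V2 = numeric())
      names(pieces) <- c("onset_s", "offset_s")
      if (nrow(pieces) == 0L) break
    }
    out[[i]] <- pieces
  }
  res <- do.call(rbind, out)
  res[res$offset_s - res$onset_s > 1e-9, , drop = FALSE]
}

#' Extract scored segments of one sleep stage
#'
#' Merges contiguous hypnogram epochs of the requested stage, removes spans
#' covered by the artifact mask, and reports the total minutes retained. If
#' fewer than \code{min_minutes} remain, the result is flagged (attribute
#' \code{below_minimum}) with a warning, but still returned, mirroring a
#' cohort-level inclusion rule that is enforced elsewhere.
#'
#' @param rec an \code{eeg_recording} (used to bound intervals)
#' @param hyp a \code{\link{hypnogram}}
#' @param stage stage label to extract (e.g. \code{"N2"})
#' @param artifact_mask optional data.frame (\code{onset_s}, \code{offset_s})
#' @param min_minutes quality threshold in minutes (default 20)
#' @return data.frame of class \code{"stage_segments"} with \code{onset_s},
#'   \code{offset_s}; attributes \code{stage}, \code{total_minutes},
#'   \code{below_minimum}
#' @export
extract_segments <- function(rec, hyp, stage, artifact_mask = NULL,
                             min_minutes = 20) {
  sel <- hyp[hyp$stage == stage, , drop = FALSE]
  if (nrow(sel) == 0L) stop("no scored epochs of stage ", stage)
  iv <- data.frame(onset_s = sel$onset_s,
                   offset_s = sel$onset_s + sel$duration_s)
  iv <- iv[order(iv$onset_s), , drop = FALSE]
  # merge contiguous/overlapping epochs
  merged <- iv[1L, , drop = FALSE]
  if (nrow(iv) > 1L) for (i in 2L:nrow(iv)) {
    last <- nrow(merged)
    if (iv$onset_s[i] <= merged$offset_s[last] + 1e-9)
      merged$offset_s[last] <- max(merged$offset_s[last], iv$offset_s[i])
    else merged <- rbind(merged, iv[i, ])
  }
  dur <- recording_duration(rec) + rec$start_time
  merged$offset_s <- pmin(merged$offset_s, dur)
  merged <- merged[merged$offset_s > merged$onset_s, , drop = FALSE]
  merged <- .subtract_intervals(merged, artifact_mask)
  total_min <- sum(merged$offset_s - merged$onset_s) / 60
  below <- total_min < min_minutes
  if (below)
    warning(sprintf("stage %s: only %.1f min retained (< %g min)",
                    stage, total_min, min_minutes), call. = FALSE)
  rownames(merged) <- NULL
  structure(merged, stage = stage, total_minutes = total_min,
            below_minimum = below,
            class = c("stage_segments", "data.frame"))
}

#' Total minutes covered by a stage_segments object
#' @param segments a \code{stage_segments}
#' @return minutes (numeric scalar)
#' @export
segment_minutes <- function(segments) attr(segments, "total_minutes")

#' Concatenate two stage_segments objects (e.g. N2 and N3)
#' @param a,b \code{stage_segments}
#' @return combined \code{stage_segments} (stage label joined with "+")
#' @export
combine_segments <- function(a, b) {
  out <- rbind(as.data.frame(a), as.data.frame(b))
  out <- out[order(out$onset_s), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            stage = paste(attr(a, "stage"), attr(b, "stage"), sep = "+"),
            total_minutes = sum(out$offset_s - out$onset_s) / 60,
            below_minimum = attr(a, "below_minimum") ||
              attr(b, "below_minimum"),
            class = c("stage_segments", "data.frame"))
}

# sample indices (1-based) covered by segments; half-open [onset, offset)
.segment_index <- function(segments, sampling_rate, n_samples,
                           start_time = 0) {
  idx <- integer(0)
  for (i in seq_len(nrow(segments))) {
    a <- floor((segments$onset_s[i] - start_time) * sampling_rate) + 1L
    b <- floor((segments$offset_s[i] - start_time) * sampling_rate)
    a <- max(a, 1L); b <- min(b, n_samples)
    if (b >= a) idx <- c(idx, a:b)
  }
  idx
}

#' Average two nights of a hemispheric feature table
#'
#' Per patient, feature and side, the pooled value is the arithmetic mean of
#' the two nights. Patients present in only one night pass through with
#' \code{single_night = TRUE}.
#'
#' @param night1,night2 hemispheric feature tables
#'   (columns \code{patient_id}, \code{feature}, \code{value_left},
#'   \code{value_right}); \code{night2} may be \code{NULL}
#' @return pooled table with \code{night = "pooled"} and a
#'   \code{single_night} logical column
#' @export
pool_nights <- function(night1, night2 = NULL) {
  n1 <- as.data.frame(night1)
  if (is.null(night2)) {
    out <- n1[c("patient_id", "feature", "value_left", "value_right")]
    out$single_night <- TRUE
  } else {
    n2 <- as.data.frame(night2)
    key1 <- paste(n1$patient_id, n1$feature, sep = "\r")
    key2 <- paste(n2$patient_id, n2$feature, sep = "\r")
    m <- match(key1, key2)
    out <- n1[c("patient_id", "feature", "value_left", "value_right")]
    have2 <- !is.na(m)
    out$value_left[have2] <-
      (n1$value_left[have2] + n2$value_left[m[have2]]) / 2
    out$value_right[have2] <-
      (n1$value_right[have2] + n2$value_right[m[have2]]) / 2
    out$single_night <- !have2
    only2 <- setdiff(key2, key1)
    if (length(only2)) {
      extra <- n2[match(only2, key2),
                  c("patient_id", "feature", "value_left", "value_right")]
      extra$single_night <- TRUE
      out <- rbind(out, extra)
    }
  }
  out$night <- "pooled"
  rownames(out) <- NULL
  out[c("patient_id", "night", "feature", "value_left", "value_right",
        "single_night")]
}
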