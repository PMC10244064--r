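# Minimal EDF (European Data Format) reader/writer.
# EDF is a fixed-layout ASCII-header + int16 little-endian format:
# 256-byte global header, 256 bytes of per-signal header fields, then data
# records with each signal's samples stored contiguously per record.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write an EEG recording to an EDF file
#'
#' 16-bit EDF with 1-second data records. Samples are scaled into a fixed
#' physical range of +/- 3276.8 microvolts (0.1 uV resolution); values outside
#' that range are clipped. The signal is truncated to a whole number of
#' records.
#'
#' @param rec an \code{\link{eeg_recording}} (microvolts)
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
write_edf <- function(rec, path) {
  fs <- rec$sampling_rate
  if (abs(fs - round(fs)) > 1e-9)
    stop("write_edf requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$signal)
  ndr <- floor(ncol(rec$signal) / fs)
  if (ndr < 1L) stop("recording shorter than one 1-s data record")
  phys_max <- 3276.8
  dig_max <- 32767L; dig_min <- -32768L
  scale <- (2 * phys_max) / (dig_max - dig_min + 1L)  # 0.1 uV / unit

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad("X X X X", 80),
    .edf_pad("Startdate X X X X", 80),
    "01.01.00", "00.00.00",
    .edf_pad(256L * (ns + 1L), 8),
    .edf_pad("", 44),
    .edf_pad(ndr, 8),
    .edf_pad(1, 8),
    .edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, .edf_pad, "", width = width),
                     collapse = ""), con, eos = NULL)
  field(paste("EEG", rec$channel_labels), 16)
  field(rep("", ns), 80)                      # transducer
  field(rep("uV", ns), 8)                     # physical dimension
  field(rep(sprintf("%g", -phys_max), ns), 8)
  field(rep(sprintf("%g", phys_max - scale), ns), 8)
  field(rep(dig_min, ns), 8)
  field(rep(dig_max, ns), 8)
  field(rep("", ns), 80)                      # prefiltering
  field(rep(fs, ns), 8)                       # samples per record
  field(rep("", ns), 32)

  dig <- round(rec$signal[, seq_len(ndr * fs), drop = FALSE] / scale)
  dig <- pmin(pmax(dig, dig_min), dig_max)
  for (r in seq_len(ndr)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF/EDF+ recording
#'
#' Reads a continuous 16-bit EDF file into an \code{\link{eeg_recording}}.
#' Channel labels are normalized to 10-20 names via
#' \code{\link{normalize_channel_labels}}. All signals must share one sampling
#' rate; annotation channels are not supported.
#'
#' @param path EDF file path
#' @param require_electrodes optional character vector; an error names any of
#'   these electrodes missing after normalization
#' @return an \code{\link{eeg_recording}}
#' @export
read_edf <- function(path, require_electrodes = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)            # patient, recording, date, time
  rd(8)                                   # header bytes
  rd(44)
  ndr <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("invalid EDF header (signal count)")
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16)
  rdv(80)                                 # transducer
  rdv(8)                                  # physical dimension
  phys_min <- as.numeric(rdv(8))
  phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8))
  dig_max <- as.numeric(rdv(8))
  rdv(80)                                 # prefiltering
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1L)
    stop("mixed per-channel sampling rates are not supported")
  fs <- spr[1L] / rec_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  n_per_rec <- sum(spr)
  sig <- matrix(0, nrow = ns, ncol = ndr * spr[1L])
  for (r in seq_len(ndr)) {
    block <- readBin(con, integer(), n = n_per_rec, size = 2L, signed = TRUE,
                     endian = "little")
    if (length(block) < n_per_rec) stop("truncated EDF data record")
    block <- matrix(block, nrow = spr[1L], ncol = ns)
    cols <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    sig[, cols] <- t(block) * gain + offset
  }
  labels <- normalize_channel_labels(labels)
  if (!is.null(require_electrodes)) {
    missing <- setdiff(require_electrodes, labels)
    if (length(missing))
      stop("recording lacks required electrode(s): ",
           paste(missing, collapse = ", "))
  }
  eeg_recording(sig, labels, fs)
}

#' Read a patient recording for the analysis pipeline
#'
#' Thin wrapper around \code{\link{read_edf}} that additionally checks for the
#' electrodes required by a montage.
#'
#' @param path EDF file path
#' @param montage bipolar montage whose electrodes must be present
#'   (default the standard 24-pair montage); \code{NULL} skips the check
#' @return an \code{\link{eeg_recording}}
#' @export
read_recording <- function(path, montage = default_montage()) {
  need <- if (is.null(montage)) NULL else montage_electrodes(montage)
  read_edf(path, require_electrodes = need)
}
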