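#' Standard longitudinal bipolar montage
#'
#' The extended longitudinal ("double banana") bipolar montage with inferior
#' temporal electrodes used throughout the package: 24 anode-cathode pairs,
#' 12 over each hemisphere, no midline pairs. Each derived trace is
#' anode minus cathode.
#'
#' @param reduced logical; if \code{TRUE}, return only the six pairs needed by
#'   the event detectors (slow waves: F3-C3, F7-T7, F4-C4, F8-T8; spindles:
#'   C3-FT9, C4-FT10), useful for fast simulations.
#' @return A data.frame of class \code{"bipolar_montage"} with columns
#'   \code{anode}, \code{cathode}, \code{side} (\code{"left"}/\code{"right"}).
#' @examples
#' m <- default_montage()
#' table(m$side)
#' @export
default_montage <- function(reduced = FALSE) {
  if (reduced) {
    m <- data.frame(
      anode   = c("F3", "F7", "C3", "F4", "F8", "C4"),
      cathode = c("C3", "T7", "FT9", "C4", "T8", "FT10"),
      side    = rep(c("left", "right"), each = 3L),
      stringsAsFactors = FALSE)
  } else {
    right <- data.frame(
      anode   = c("Fp2", "F10", "FT10", "P10", "Fp2", "F8", "T8", "P8",
                  "Fp2", "F4", "C4", "P4"),
      cathode = c("F10", "FT10", "P10", "O2", "F8", "T8", "P8", "O2",
                  "F4", "C4", "P4", "O2"),
      stringsAsFactors = FALSE)
    left <- data.frame(
      anode   = c("Fp1", "F9", "FT9", "P9", "Fp1", "F7", "T7", "P7",
                  "Fp1", "F3", "C3", "P3"),
      cathode = c("F9", "FT9", "P9", "O1", "F7", "T7", "P7", "O1",
                  "F3", "C3", "P3", "O1"),
      stringsAsFactors = FALSE)
    right$side <- "right"; left$side <- "left"
    m <- rbind(right, left)
  }
  class(m) <- c("bipolar_montage", "data.frame")
  m
}

#' Electrodes referenced by a bipolar montage
#' @param montage a \code{bipolar_montage}
#' @return character vector of unique electrode labels
#' @export
montage_electrodes <- function(montage) {
  unique(c(montage$anode, montage$cathode))
}

#' Channels used for slow-wave detection (bipolar labels)
#' @return character vector of four bipolar channel names
#' @export
slow_wave_channels <- function() c("F3-C3", "F7-T7", "F4-C4", "F8-T8")

#' Channels used for spindle detection (bipolar labels), one per hemisphere
#' @return named character vector (\code{left}, \code{right})
#' @export
spindle_channels <- function() c(left = "C3-FT9", right = "C4-FT10")

# old-nomenclature aliases resolved during label normalization
.label_aliases <- c(T3 = "T7", T4 = "T8", T5 = "P7", T6 = "P8")

#' Normalize an EEG channel label to its 10-20 name
#'
#' Strips an \code{"EEG "} prefix and a reference suffix (anything after a
#' \code{"-"}), matches case-insensitively against the 10-20 nomenclature and
#' resolves old-style aliases (T3 to T7, T4 to T8, T5 to P7, T6 to P8).
#'
#' @param labels character vector of raw channel labels
#' @return character vector of normalized labels (capitalization canonical for
#'   recognized 10-20 names; unrecognized labels are returned trimmed)
#' @examples
#' normalize_channel_labels(c("EEG Fp1-Ref", "t3", "C4"))
#' @export
normalize_channel_labels <- function(labels) {
  canon <- c("Fp1", "Fp2", "Fpz", "F3", "F4", "F7", "F8", "F9", "F10", "Fz",
             "FT9", "FT10", "C3", "C4", "Cz", "T7", "T8", "P3", "P4", "P7",
             "P8", "P9", "P10", "Pz", "O1", "O2", "Oz", "A1", "A2", "M1", "M2")
  out <- trimws(labels)
  out <- sub("^EEG[ _]+", "", out, ignore.case = TRUE)
  out <- sub("-.*$", "", out)   # drop reference suffix, e.g. "Fp1-Ref"
  out <- trimws(out)
  up <- toupper(out)
  hit <- match(up, toupper(canon))
  out[!is.na(hit)] <- canon[hit[!is.na(hit)]]
  ali <- match(up, names(.label_aliases))
  out[!is.na(ali)] <- unname(.label_aliases[ali[!is.na(ali)]])
  out
}
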