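# Signal-processing primitives shared by the detectors.

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth applied forward and backward
#' (\code{signal::filtfilt}), so the effective magnitude response is squared
#' and the phase response is zero; trough timings are preserved.
#'
#' @param x numeric vector
#' @param sampling_rate Hz
#' @param band length-2 numeric, band edges in Hz
#' @param order filter order (default 4)
#' @return filtered vector, same length as \code{x}
#' @export
bandpass_filter <- function(x, sampling_rate, band, order = 4L) {
  ny <- sampling_rate / 2
  if (band[2] >= ny) stop("band edge at or above Nyquist")
  bf <- signal::butter(order, band / ny, type = "pass")
  signal::filtfilt(bf, x)
}

#' Analytic signal via the Hilbert transform
#'
#' FFT construction of the analytic signal: positive frequencies doubled,
#' negative frequencies zeroed. \code{instantaneous_phase} returns the phase
#' under the cosine convention (0 at a signal maximum, +/- pi at a trough,
#' -pi/2 at a rising zero-crossing).
#'
#' @param x real numeric vector
#' @return \code{hilbert_analytic}: complex vector of the same length
#' @export
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' @rdname hilbert_analytic
#' @export
instantaneous_phase <- function(x) Arg(hilbert_analytic(x))

#' Welch power spectral density
#'
#' Averaged modified periodograms: Hamming-windowed segments of
#' \code{window_s} seconds with fractional \code{overlap}, one-sided density
#' scaling (integrates to the signal variance).
#'
#' @param x numeric vector
#' @param sampling_rate Hz
#' @param window_s window length in seconds (default 4)
#' @param overlap fractional window overlap (default 0.5)
#' @return list with \code{freq} (Hz) and \code{psd} (power per Hz)
#' @export
welch_psd <- function(x, sampling_rate, window_s = 4, overlap = 0.5) {
  nwin <- round(window_s * sampling_rate)
  if (length(x) < nwin)
    stop("signal shorter than one Welch window (", window_s, " s)")
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nwin - 1)) / (nwin - 1))  # Hamming
  u <- sum(w^2)
  acc <- numeric(nwin %/% 2 + 1L)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1L)] * w
    X <- stats::fft(seg)
    p <- Mod(X[seq_along(acc)])^2
    acc <- acc + p
  }
  psd <- acc / (length(starts) * sampling_rate * u)
  # one-sided: double everything but DC (and Nyquist when nwin even)
  dbl <- 2:(length(psd) - if (nwin %% 2 == 0) 1L else 0L)
  psd[dbl] <- 2 * psd[dbl]
  list(freq = (seq_along(psd) - 1L) * sampling_rate / nwin, psd = psd)
}

#' Band power from a Welch PSD
#' @param psd result of \code{\link{welch_psd}}
#' @param band length-2 numeric band in Hz (edges inclusive)
#' @return integrated power (rectangle rule over PSD bins)
#' @export
band_power <- function(psd, band) {
  df <- psd$freq[2] - psd$freq[1]
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  sum(psd$psd[sel]) * df
}

#' Root-mean-square envelope with a centered moving window
#' @param x numeric vector
#' @param sampling_rate Hz
#' @param window_s RMS window length in seconds (default 0.2)
#' @return envelope vector, same length as \code{x}
#' @export
rms_envelope <- function(x, sampling_rate, window_s = 0.2) {
  n <- max(1L, round(window_s * sampling_rate))
  if (n %% 2 == 0L) n <- n + 1L      # centered window
  k <- rep(1 / n, n)
  ma <- stats::filter(x^2, k, sides = 2)
  ma <- as.numeric(ma)
  # pad the edges with the nearest defined value
  first <- which(!is.na(ma))[1L]
  last <- max(which(!is.na(ma)))
  ma[seq_len(first - 1L)] <- ma[first]
  if (last < length(ma)) ma[(last + 1L):length(ma)] <- ma[last]
  sqrt(pmax(ma, 0))
}

# runs of TRUE in a logical vector -> matrix of (start, end) indices
.true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}
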