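#' Multi-channel EEG recording
#'
#' @param data `channels x samples` numeric matrix (microvolts).
#' @param channel_labels 10-20 channel names, one per row.
#' @param fs Sampling rate in Hz.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, channel_labels, fs) {
  stopifnot(is.matrix(data), length(channel_labels) == nrow(data), fs > 0)
  structure(list(data = data, channel_labels = as.character(channel_labels), fs = fs),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", round(ncol(x$data) / x$fs, 2), " s)\n",
      "  channels: ", paste(x$channel_labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Select and reorder channels
#'
#' Keeps the requested channels in the requested order (case-insensitive
#' label match). The default montage is the four fatigue-sensitive sites
#' P4, C3, O1, O2.
#'
#' @param rec An [eeg_recording].
#' @param names Channel labels to keep, in output order.
#' @return An [eeg_recording] with `length(names)` rows.
#' @export
select_channels <- function(rec, names = c("P4", "C3", "O1", "O2")) {
  stopifnot(inherits(rec, "eeg_recording"))
  pos <- match(toupper(names), toupper(rec$channel_labels))
  if (anyNA(pos)) {
    stop("channel(s) not present in recording: ",
         paste(names[is.na(pos)], collapse = ", "))
  }
  eeg_recording(rec$data[pos, , drop = FALSE], rec$channel_labels[pos], rec$fs)
}

# Design the second-order bandstop (notch) biquad at f0 with quality Q.
# Standard constrained direct-form biquad: unit gain at DC and Nyquist,
# zero at f0, bandwidth ~ f0/Q.
design_notch <- function(f0, fs, Q = 30) {
  if (f0 <= 0 || f0 >= fs / 2) stop("notch frequency must lie strictly below Nyquist = ", fs / 2)
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Cascade of second-order Butterworth high-pass and low-pass sections.
design_bandpass <- function(lo, hi, fs, order = 2) {
  if (!(lo > 0 && lo < hi && hi < fs / 2)) {
    stop("band edges must satisfy 0 < lo < hi < Nyquist = ", fs / 2)
  }
  list(hp = signal::butter(order, lo / (fs / 2), type = "high"),
       lp = signal::butter(order, hi / (fs / 2), type = "low"))
}

# Complex frequency response of a rational digital filter at f (Hz).
filter_response <- function(b, a, f, fs) {
  w <- 2 * pi * f / fs
  z <- exp(-1i * outer(w, seq_along(b) - 1))
  num <- drop(z %*% b)
  z <- exp(-1i * outer(w, seq_along(a) - 1))
  num / drop(z %*% a)
}

#' Frequency response of the notch filter
#'
#' Single-pass complex response of the designed notch biquad (the
#' zero-phase application in [notch_filter()] has magnitude equal to the
#' square of this response's magnitude).
#'
#' @param f Frequencies in Hz.
#' @param fs Sampling rate in Hz.
#' @param f0 Notch center frequency.
#' @param Q Quality factor (bandwidth ~ `f0/Q`).
#' @return Complex vector `H(f)`.
#' @export
notch_response <- function(f, fs, f0 = 50, Q = 30) {
  d <- design_notch(f0, fs, Q)
  filter_response(d$b, d$a, f, fs)
}

#' Frequency response of the Butterworth band-pass cascade
#'
#' @inheritParams notch_response
#' @param lo,hi Band edges in Hz.
#' @param order Order of each (high-pass and low-pass) section.
#' @return Complex vector `H(f)` (single-pass).
#' @export
bandpass_response <- function(f, fs, lo = 0.02, hi = 50, order = 2) {
  d <- design_bandpass(lo, hi, fs, order)
  filter_response(d$hp$b, d$hp$a, f, fs) * filter_response(d$lp$b, d$lp$a, f, fs)
}

# Zero-phase (forward-backward) filtering of each row of a matrix.
filtfilt_rows <- function(b, a, x) {
  if (is.matrix(x)) {
    t(apply(x, 1, function(r) signal::filtfilt(b, a, r)))
  } else {
    signal::filtfilt(b, a, x)
  }
}

#' Mains notch filter
#'
#' Second-order bandstop (notch) biquad applied forward-backward
#' (zero-phase) to every channel. Removes the 50 Hz city-electricity tone
#' while leaving the passband within 1 dB.
#'
#' @param x Numeric vector or `channels x samples` matrix.
#' @param fs Sampling rate in Hz.
#' @param f0 Notch frequency in Hz (default 50); must be below Nyquist.
#' @param Q Quality factor (default 30).
#' @return Filtered signal, same shape as `x`.
#' @export
notch_filter <- function(x, fs, f0 = 50, Q = 30) {
  d <- design_notch(f0, fs, Q)
  filtfilt_rows(d$b, d$a, x)
}

#' Butterworth band-pass filter
#'
#' Second-order Butterworth band-pass realized as a cascade of a
#' second-order high-pass at `lo` and a second-order low-pass at `hi`,
#' applied forward-backward (zero-phase) per channel. With the default
#' 0.02 Hz edge the high-pass has a ~50 s period and is effectively inert
#' on signals shorter than about a minute; filter full recordings before
#' extracting terminal windows.
#'
#' @inheritParams notch_filter
#' @param lo,hi Band edges in Hz (defaults 0.02 and 50).
#' @param order Order of each section (default 2).
#' @return Filtered signal, same shape as `x`.
#' @export
bandpass_butterworth <- function(x, fs, lo = 0.02, hi = 50, order = 2) {
  d <- design_bandpass(lo, hi, fs, order)
  x <- filtfilt_rows(d$hp$b, d$hp$a, x)
  filtfilt_rows(d$lp$b, d$lp$a, x)
}

#' Extract the terminal window of a recording
#'
#' Returns the final `round(window_s * fs)` samples of every channel —
#' the minimal-window detection scheme keeps only the last seconds of
#' each recording. Sample intervals are 0-based and half-open.
#'
#' @param rec An [eeg_recording].
#' @param window_s Window duration in seconds (default 5).
#' @return List of class `eeg_window` with fields `data`
#'   (channels x window-length), `fs`, `channel_labels`, `interval`
#'   (0-based half-open `[start, end)`) and `label` (`NA`).
#' @export
extract_terminal_window <- function(rec, window_s = 5) {
  stopifnot(inherits(rec, "eeg_recording"))
  L <- as.integer(round(window_s * rec$fs))
  N <- ncol(rec$data)
  if (N < L) stop("recording too short: ", N, " samples < window of ", L)
  structure(list(data = rec$data[, (N - L + 1):N, drop = FALSE], fs = rec$fs,
                 channel_labels = rec$channel_labels,
                 interval = c(N - L, N), label = NA_integer_),
            class = "eeg_window")
}

#' Min-max normalization to [0, 1]
#'
#' Per-channel affine rescaling `(x - min) / (max - min)`. Constant
#' channels cannot be rescaled; they map to all-zeros with a warning.
#'
#' @param x Numeric vector or `channels x samples` matrix of finite
#'   values.
#' @return Same shape as `x`, each non-constant channel spanning [0, 1].
#' @export
minmax_normalize <- function(x) {
  if (!all(is.finite(x))) stop("minmax_normalize requires finite values")
  scale1 <- function(r) {
    rng <- range(r)
    if (rng[1] == rng[2]) {
      warning("constant channel mapped to zeros in min-max normalization")
      return(rep(0, length(r)))
    }
    (r - rng[1]) / (rng[2] - rng[1])
  }
  if (is.matrix(x)) t(apply(x, 1, scale1)) else scale1(x)
}

#' Signal-conditioning chain for a windowed dataset
#'
#' Applies the offline conditioning used before classification: 50 Hz
#' notch, 0.02-50 Hz Butterworth band-pass, and per-channel min-max
#' normalization, window by window. Windows are assumed already cut (the
#' terminal-window step applies to full recordings).
#'
#' @param ds A [windowed_dataset] of raw windows (microvolts).
#' @param notch_f0 Notch frequency in Hz (`NULL` skips the notch).
#' @param band Band edges in Hz (`NULL` skips the band-pass).
#' @param normalize Apply min-max normalization (default TRUE).
#' @return A [windowed_dataset] of conditioned windows.
#' @export
preprocess_windows <- function(ds, notch_f0 = 50, band = c(0.02, 50),
                               normalize = TRUE) {
  stopifnot(inherits(ds, "windowed_dataset"))
  if (!is.null(notch_f0)) ds <- map_windows(ds, notch_filter, fs = ds$fs, f0 = notch_f0)
  if (!is.null(band)) {
    ds <- map_windows(ds, bandpass_butterworth, fs = ds$fs, lo = band[1], hi = band[2])
  }
  if (normalize) ds <- map_windows(ds, minmax_normalize)
  ds
}
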