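#' Fatigue class specification
#'
#' Describes one ordinal fatigue class by its relative EEG band-power
#' profile and white-noise floor. Class ids follow the five-stage scheme
#' 0 = normal, 1 = alert-for-fatigue, 2 = semi-fatigue, 3 = fatigue,
#' 4 = full-fatigue.
#'
#' @param class_id Integer in 0..4.
#' @param band_powers Named list/vector of non-negative relative powers for
#'   the bands in [eeg_bands()] (dimensionless).
#' @param noise_floor White-noise standard deviation in microvolts.
#' @return Object of class `fatigue_class_spec`.
#' @export
fatigue_class_spec <- function(class_id, band_powers, noise_floor = 3) {
  class_id <- as.integer(class_id)
  stopifnot(length(class_id) == 1, class_id >= 0, class_id <= 4)
  band_powers <- as.list(band_powers)
  known <- names(eeg_bands())
  stopifnot(all(names(band_powers) %in% known))
  if (any(unlist(band_powers) < 0)) stop("band powers must be non-negative")
  stopifnot(noise_floor >= 0)
  structure(list(class_id = class_id, band_powers = band_powers,
                 noise_floor = noise_floor),
            class = "fatigue_class_spec")
}

#' Default five-class fatigue gradient
#'
#' The default cohort's band-power profiles encode the monotone fatigue
#' gradient reported for drowsiness EEG: theta power rises and beta power
#' falls with deepening fatigue, while alpha rises mildly (eyes-open
#' resting fatigue). Values are relative powers; the absolute scale is set
#' by the generator's `amplitude` argument.
#'
#' @param noise_floor White-noise standard deviation in microvolts shared
#'   by all classes.
#' @return List of five [fatigue_class_spec] objects (class ids 0..4).
#' @export
default_fatigue_classes <- function(noise_floor = 3) {
  delta <- c(0.6, 0.7, 0.8, 0.9, 1.0)
  theta <- c(0.4, 0.6, 0.9, 1.3, 1.8)
  alpha <- c(0.8, 0.9, 1.0, 1.1, 1.2)
  beta  <- c(1.0, 0.85, 0.7, 0.55, 0.4)
  lapply(0:4, function(k) {
    fatigue_class_spec(k, list(delta = delta[k + 1], theta = theta[k + 1],
                               alpha = alpha[k + 1], beta = beta[k + 1]),
                       noise_floor = noise_floor)
  })
}

#' Cohort specification
#'
#' Conditions under which a synthetic cohort is generated. Defaults match
#' the recording setup the classifier targets: four channels (P4, C3, O1,
#' O2) sampled at 250 Hz in 5-s windows with 50 Hz mains contamination.
#'
#' @param classes List of [fatigue_class_spec]; default the five-class
#'   gradient of [default_fatigue_classes()].
#' @param n_windows_per_class Windows generated per class.
#' @param n_channels Number of channels (default 4).
#' @param fs Sampling rate in Hz (default 250). Must exceed twice the
#'   highest band edge.
#' @param window_s Window duration in seconds (default 5); `window_s * fs`
#'   must be a whole number.
#' @param mains_amplitude Amplitude of the injected 50 Hz mains tone in
#'   microvolts (default 10; set 0 to disable).
#' @param seed Integer seed controlling the whole cohort.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(classes = default_fatigue_classes(),
                        n_windows_per_class = 100L,
                        n_channels = 4L, fs = 250, window_s = 5,
                        mains_amplitude = 10, seed = 1L) {
  stopifnot(length(classes) >= 1, all(vapply(classes, inherits, TRUE, "fatigue_class_spec")))
  ids <- vapply(classes, `[[`, 0L, "class_id")
  if (anyDuplicated(ids)) stop("duplicate class_ids in cohort spec")
  hi <- max(vapply(eeg_bands(), `[`, 0, 2))
  if (fs <= 2 * hi) stop("fs must exceed twice the highest band edge (", 2 * hi, " Hz)")
  n_samples <- window_s * fs
  if (abs(n_samples - round(n_samples)) > 1e-9) stop("window_s * fs must be an integer")
  structure(list(classes = classes, n_windows_per_class = as.integer(n_windows_per_class),
                 n_channels = as.integer(n_channels), fs = fs, window_s = window_s,
                 mains_amplitude = mains_amplitude, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Unit-RMS random-phase sinusoid mixture confined to a band: a fixed,
# evenly spaced frequency comb over the band interior with phases drawn
# uniformly per call. Randomizing phases (not frequencies) keeps each
# class's spectral support stable across windows, which is what makes
# the cohort learnable from band content.
band_mixture <- function(t, edges, n_sinusoids = 5L) {
  f <- edges[1] + (seq_len(n_sinusoids) - 0.5) / n_sinusoids * (edges[2] - edges[1])
  phi <- stats::runif(n_sinusoids, 0, 2 * pi)
  x <- sin(outer(f, t, function(f, t) 2 * pi * f * t) + phi)
  colSums(x) / sqrt(n_sinusoids / 2)
}

#' Generate one synthetic EEG window
#'
#' Each channel is a sum over bands of random-phase sinusoid mixtures
#' (five sinusoids per band, exactly band-limited) scaled by the class's
#' relative band powers, plus Gaussian white noise. Within every band the
#' channels blend a shared latent mixture with an independent one
#' (`shared_weight`), so that inter-channel correlation is strictly
#' between 0 and 1 in expectation — the functional-connectivity graph
#' downstream needs non-degenerate correlations.
#'
#' @param spec A [fatigue_class_spec].
#' @param n_channels,n_samples Output dimensions (`n_samples >= 2`).
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed; the output is a pure function of
#'   `(spec, dims, fs, seed)`.
#' @param shared_weight Amplitude weight of the shared latent band process
#'   (default 0.5; the shared/independent mixture is renormalized to unit
#'   RMS).
#' @param amplitude Scale in microvolts applied to each unit-RMS band
#'   mixture; the default 10 makes raw default-class windows span roughly
#'   +/- 50 microvolts.
#' @return `n_channels x n_samples` numeric matrix (microvolts).
#' @export
generate_window <- function(spec, n_channels, n_samples, fs, seed = NULL,
                            shared_weight = 0.5, amplitude = 10) {
  stopifnot(inherits(spec, "fatigue_class_spec"))
  if (n_channels < 1 || n_samples < 2) stop("non-positive or degenerate dimensions")
  if (fs <= 0) stop("fs must be positive")
  bands <- eeg_bands()
  norm <- sqrt(shared_weight^2 + (1 - shared_weight)^2)
  local_seed(seed, {
    t <- (seq_len(n_samples) - 1) / fs
    out <- matrix(0, n_channels, n_samples)
    for (bn in names(spec$band_powers)) {
      p <- spec$band_powers[[bn]]
      if (p <= 0) next
      shared <- band_mixture(t, bands[[bn]])
      for (ch in seq_len(n_channels)) {
        indep <- band_mixture(t, bands[[bn]])
        mix <- (shared_weight * shared + (1 - shared_weight) * indep) / norm
        out[ch, ] <- out[ch, ] + amplitude * sqrt(p) * mix
      }
    }
    if (spec$noise_floor > 0) {
      out <- out + matrix(stats::rnorm(n_channels * n_samples, sd = spec$noise_floor),
                          n_channels, n_samples)
    }
    out
  })
}

#' Inject a mains-frequency tone
#'
#' Adds `amplitude * sin(2 pi f0 t + phi)` to every channel, with an
#' independent random phase per channel. Emulates 50 Hz city-electricity
#' contamination that the notch stage removes downstream.
#'
#' @param window channels x samples matrix.
#' @param fs Sampling rate in Hz.
#' @param f0 Tone frequency in Hz; must lie below Nyquist.
#' @param amplitude Tone amplitude (microvolts); 0 returns the input.
#' @param seed Integer seed for the channel phases.
#' @return Matrix of the same shape.
#' @export
inject_mains <- function(window, fs, f0 = 50, amplitude = 10, seed = NULL) {
  stopifnot(is.matrix(window), fs > 0)
  if (f0 <= 0 || f0 >= fs / 2) stop("f0 must lie strictly between 0 and fs/2 = ", fs / 2)
  if (amplitude == 0) return(window)
  local_seed(seed, {
    t <- (seq_len(ncol(window)) - 1) / fs
    phi <- stats::runif(nrow(window), 0, 2 * pi)
    window + amplitude * sin(outer(phi, 2 * pi * f0 * t, `+`))
  })
}

#' Add white noise at an exact signal-to-noise ratio
#'
#' Draws Gaussian noise, rescales the realization so the empirical
#' `10*log10(P_signal / P_noise)` equals `snr_db` exactly, and adds it.
#'
#' @param window channels x samples matrix with non-zero power.
#' @param snr_db Target SNR in dB.
#' @param seed Integer seed.
#' @return Corrupted matrix of the same shape.
#' @export
add_white_noise_snr <- function(window, snr_db, seed = NULL) {
  stopifnot(is.matrix(window), is.finite(snr_db))
  p_sig <- mean(window^2)
  if (p_sig == 0) stop("SNR undefined for an all-zero window")
  local_seed(seed, {
    z <- matrix(stats::rnorm(length(window)), nrow(window))
    z <- z / sqrt(mean(z^2)) * sqrt(p_sig * 10^(-snr_db / 10))
    window + z
  })
}

#' Generate a labeled synthetic cohort
#'
#' Draws `n_windows_per_class` windows for every class in the spec,
#' injects the mains tone, and returns a balanced labeled
#' [windowed_dataset]. Every window's seed is derived from the cohort seed
#' and recorded in the provenance table, so any window can be regenerated
#' in isolation.
#'
#' @param cohort A [cohort_spec].
#' @param channel_labels Channel names (default the four-channel montage
#'   P4, C3, O1, O2 when `n_channels == 4`).
#' @return A [windowed_dataset] with `n_classes * n_windows_per_class`
#'   windows and exactly balanced labels.
#' @export
generate_cohort <- function(cohort, channel_labels = NULL) {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (length(cohort$classes) < 2) stop("cohort needs at least 2 classes")
  if (cohort$n_windows_per_class < 1) stop("n_windows_per_class must be >= 1")
  if (is.null(channel_labels)) {
    channel_labels <- if (cohort$n_channels == 4) c("P4", "C3", "O1", "O2") else
      paste0("ch", seq_len(cohort$n_channels))
  }
  n_samples <- as.integer(round(cohort$window_s * cohort$fs))
  n_total <- length(cohort$classes) * cohort$n_windows_per_class
  data <- array(0, c(cohort$n_channels, n_samples, n_total))
  labels <- integer(n_total)
  seeds <- double(n_total)
  idx <- 0L
  for (cls in cohort$classes) {
    for (w in seq_len(cohort$n_windows_per_class)) {
      idx <- idx + 1L
      ws <- derive_seed(cohort$seed, cls$class_id + 1L, w)
      win <- generate_window(cls, cohort$n_channels, n_samples, cohort$fs, seed = ws)
      if (cohort$mains_amplitude > 0 && 50 < cohort$fs / 2) {
        win <- inject_mains(win, cohort$fs, 50, cohort$mains_amplitude,
                            seed = derive_seed(ws, 7L))
      }
      data[, , idx] <- win
      labels[idx] <- cls$class_id
      seeds[idx] <- ws
    }
  }
  windowed_dataset(data, labels, fs = cohort$fs, channel_labels = channel_labels,
                   provenance = data.frame(window_id = seq_len(n_total),
                                           class_id = labels, seed = seeds,
                                           synthetic = FALSE))
}
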