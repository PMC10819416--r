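#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the global stream untouched (draws consume it).
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive a child seed from a base seed and a stage/index pair, kept < 2^31.
derive_seed <- function(seed, stage, index = 0L) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 10007 + as.double(stage) * 101 + as.double(index)) %% 2147483629
}

#' Canonical EEG frequency bands
#'
#' Band edges in Hz for the delta, theta, alpha and beta rhythms used
#' throughout the package (half-open intervals `[lo, hi)`).
#'
#' @return Named list of length-2 numeric vectors (Hz).
#' @export
eeg_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

#' Periodogram band power
#'
#' One-sided periodogram power of a signal integrated over a frequency band.
#' Used by the synthetic-cohort checks and the band-power baseline
#' classifier; not a substitute for a full spectral-estimation toolkit.
#'
#' @param x Numeric vector (one channel).
#' @param fs Sampling rate in Hz.
#' @param band Length-2 numeric, band edges in Hz (half-open `[lo, hi)`).
#' @return Scalar power (signal units squared).
#' @export
band_power <- function(x, fs, band) {
  stopifnot(is.numeric(x), length(x) >= 2, fs > 0, length(band) == 2, band[1] < band[2])
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n^2
  f <- (seq_len(n) - 1) * fs / n
  half <- seq_len(floor(n / 2) + 1)
  sel <- half[f[half] >= band[1] & f[half] < band[2]]
  2 * sum(p[sel])
}

# Per-window band-power feature matrix (windows x (channels*bands)).
# Exported because it backs the linear baseline used to certify cohort
# learnability.

#' Band-power features for a windowed dataset
#'
#' @param ds A [windowed_dataset].
#' @param bands Named list of band edges, default [eeg_bands()].
#' @param log Take log10 of powers (stabilizes the linear baseline).
#' @return Numeric matrix, one row per window.
#' @export
band_power_features <- function(ds, bands = eeg_bands(), log = TRUE) {
  stopifnot(inherits(ds, "windowed_dataset"))
  d <- dim(ds$data)
  feat <- matrix(0, d[3], d[1] * length(bands))
  for (w in seq_len(d[3])) {
    col <- 1L
    for (ch in seq_len(d[1])) {
      for (b in bands) {
        feat[w, col] <- band_power(ds$data[ch, , w], ds$fs, b)
        col <- col + 1L
      }
    }
  }
  if (log) feat <- log10(feat + 1e-12)
  colnames(feat) <- as.vector(outer(names(bands), seq_len(d[1]),
                                    function(b, c) paste0("ch", c, "_", b)))
  feat
}
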