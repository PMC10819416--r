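#' Accuracy under additive white noise (SNR sweep)
#'
#' Corrupts raw test windows with Gaussian white noise at each requested
#' SNR (via [add_white_noise_snr()]), re-applies the conditioning chain,
#' and reports classification accuracy. A no-noise reference row
#' (`snr_db = Inf`) is always included.
#'
#' @param model A trained classifier (see [evaluate_model()]).
#' @param test_raw A labeled [windowed_dataset] of raw (unnormalized)
#'   windows.
#' @param snr_list_db Numeric vector of SNRs in dB (non-empty).
#' @param seed Integer seed (one independent noise realization per
#'   window per SNR).
#' @param preprocess Function applied to the (corrupted) dataset before
#'   prediction; default the standard notch + band-pass + min-max chain.
#' @return data.frame with columns `snr_db` and `accuracy`, first row
#'   the clean reference.
#' @export
snr_robustness_sweep <- function(model, test_raw, snr_list_db, seed = 1L,
                                 preprocess = preprocess_windows) {
  stopifnot(inherits(test_raw, "windowed_dataset"))
  if (length(snr_list_db) == 0) stop("snr_list_db must be non-empty")
  if (all(is.na(test_raw$labels))) stop("test set must be labeled")
  acc_of <- function(ds) {
    mean(predict(model, preprocess(ds)) == ds$labels)
  }
  out <- data.frame(snr_db = c(Inf, snr_list_db), accuracy = NA_real_)
  out$accuracy[1] <- acc_of(test_raw)
  for (i in seq_along(snr_list_db)) {
    corrupted <- test_raw
    for (w in seq_len(n_windows(test_raw))) {
      corrupted$data[, , w] <- add_white_noise_snr(
        test_raw$data[, , w], snr_list_db[i],
        seed = derive_seed(seed, 17L + i, w))
    }
    out$accuracy[i + 1] <- acc_of(corrupted)
  }
  out
}
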