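#' Desk-scale learning benchmark
#'
#' The package's standard reduced-scale training run: simulate the
#' default cohort restricted to a case's classes (100 windows per class,
#' 0.5-s windows at 128 Hz), condition it, split 70/20/10, and train the
#' reduced five-layer architecture for 30 epochs with Adamax
#' (learning rate 1e-2, weight decay 1e-1, batch 16, spectral first-layer
#' initialization). Used by the acceptance checks and as a quick sanity
#' benchmark.
#'
#' @param case_id Case id (`"I"`..`"IV"`).
#' @param seed Integer master seed.
#' @param epochs Training epochs (default 30).
#' @param n_windows_per_class Cohort size per class (default 100).
#' @return List with the trained `model`, the preprocessed `splits`, the
#'   raw splits (`splits_raw`), `val_accuracy` and `test_accuracy`.
#' @export
smoke_learning_run <- function(case_id = "I", seed = 1L, epochs = 30L,
                               n_windows_per_class = 100L) {
  case <- define_case(case_id)
  co <- cohort_spec(classes = default_fatigue_classes()[case$class_subset + 1L],
                    n_windows_per_class = n_windows_per_class,
                    fs = 128, window_s = 0.5, seed = derive_seed(seed, 1L))
  ds <- generate_cohort(co)
  splits_raw <- split_dataset(ds, seed = derive_seed(seed, 2L))
  splits <- lapply(splits_raw, preprocess_windows)
  arch <- smoke_architecture(n_classes = length(case$class_subset))
  ctrl <- gcn_control(epochs = epochs, learning_rate = 1e-2, weight_decay = 1e-1,
                      batch_size = 16L, seed = derive_seed(seed, 5L))
  model <- fatigue_gcn(splits$train, splits$val, arch = arch, control = ctrl,
                       graph_threshold = 0.4)
  list(model = model, splits = splits, splits_raw = splits_raw,
       val_accuracy = model$val_accuracy,
       test_accuracy = mean(predict(model, splits$test) == splits$test$labels))
}
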