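#' Default pipeline configuration
#'
#' Desk-scale end-to-end configuration: simulate a five-class cohort,
#' condition it, split 70/20/10, augment the training split per class,
#' estimate the channel graph from the training split, train the
#' classifier for the chosen case, and evaluate.
#'
#' @param case Case id (`"I"`..`"IV"`).
#' @param n_windows_per_class Cohort size per class.
#' @param fs,window_s Sampling rate and window length of the simulated
#'   cohort (default 128 Hz / 0.5 s, giving 64-sample windows that match
#'   the reduced architecture).
#' @param augment_target Per-class training-window count after GAN
#'   augmentation (`NULL` disables augmentation).
#' @param gan_iterations GAN optimizer steps per class.
#' @param epochs,batch_size,learning_rate,weight_decay Classifier
#'   training settings.
#' @param graph_threshold Adjacency sparsification threshold.
#' @param seed Master seed; all stage seeds derive from it.
#' @return Nested configuration list.
#' @export
pipeline_config <- function(case = "I", n_windows_per_class = 100L,
                            fs = 128, window_s = 0.5,
                            augment_target = NULL, gan_iterations = 100L,
                            epochs = 30L, batch_size = 16L,
                            learning_rate = 1e-2, weight_decay = 1e-1,
                            graph_threshold = 0.4, seed = 1L) {
  list(simulate = list(n_windows_per_class = n_windows_per_class, fs = fs,
                       window_s = window_s, mains_amplitude = 10),
       preprocess = list(notch_f0 = 50, band = c(0.02, 50), normalize = TRUE),
       split = list(fractions = c(0.7, 0.2, 0.1)),
       augment = list(target = augment_target, iterations = gan_iterations,
                      learning_rate = 0.001, batch_size = 10L, splits = "train"),
       graph = list(threshold = graph_threshold),
       train = list(case = case, epochs = epochs, batch_size = batch_size,
                    learning_rate = learning_rate, weight_decay = weight_decay),
       seed = as.integer(seed))
}

#' Run the full fatigue-detection pipeline
#'
#' Executes simulate -> preprocess -> split -> augment (training split
#' only) -> graph (training split only) -> train -> evaluate, writing
#' `metrics.json`, `confusion.csv`, `roc.csv`, `history.csv` and
#' `config.yaml` under `out_dir`. Augmentation and graph estimation are
#' guarded against leakage: requesting them on any split other than
#' `"train"` aborts.
#'
#' @param config A [pipeline_config()] list, or path to an equivalent
#'   YAML file.
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with the fitted model, the splits, the
#'   metrics report and the output directory.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  if (!identical(config$augment$splits, "train")) {
    stop("pipeline stage [augment] refused: augmentation may only be fitted on ",
         "the training split (got: ", paste(config$augment$splits, collapse = ", "), ")")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  case <- define_case(config$train$case %||% "I")

  cohort_raw <- stage("simulate", {
    classes <- default_fatigue_classes()[case$class_subset + 1L]
    generate_cohort(cohort_spec(
      classes = classes,
      n_windows_per_class = config$simulate$n_windows_per_class,
      fs = config$simulate$fs, window_s = config$simulate$window_s,
      mains_amplitude = config$simulate$mains_amplitude %||% 10,
      seed = derive_seed(seed, 1L)))
  })
  splits_raw <- stage("split", {
    split_dataset(cohort_raw, unlist(config$split$fractions), seed = derive_seed(seed, 2L))
  })
  splits <- stage("preprocess", {
    lapply(splits_raw, preprocess_windows,
           notch_f0 = config$preprocess$notch_f0,
           band = unlist(config$preprocess$band),
           normalize = config$preprocess$normalize %||% TRUE)
  })
  train_ds <- splits$train
  if (!is.null(config$augment$target)) {
    train_ds <- stage("augment", {
      parts <- lapply(sort(unique(train_ds$labels)), function(cl) {
        cw <- subset_windows(train_ds, which(train_ds$labels == cl))
        out <- augment_to_count(
          cw, target_count = config$augment$target,
          config = gan_config(learning_rate = config$augment$learning_rate %||% 0.001,
                              iterations = config$augment$iterations %||% 100L,
                              batch_size = config$augment$batch_size %||% 10L,
                              seed = derive_seed(seed, 4L, cl)))
        attr(out, "gan") <- NULL
        out
      })
      do.call(bind_windows, parts)
    })
  }
  graph <- stage("graph", {
    channel_graph(train_ds, threshold = config$graph$threshold %||% 0.4)
  })
  model <- stage("train", {
    L <- dim(train_ds$data)[2]
    arch <- architecture_spec(
      feature_chain = c(L, L, as.integer(L / 2), as.integer(L / 4),
                        as.integer(L / 8), as.integer(L / 8)),
      n_nodes = dim(train_ds$data)[1], n_classes = length(case$class_subset))
    ctrl <- gcn_control(epochs = config$train$epochs %||% 30L,
                        learning_rate = config$train$learning_rate %||% 1e-2,
                        weight_decay = config$train$weight_decay %||% 1e-1,
                        batch_size = config$train$batch_size %||% 16L,
                        seed = derive_seed(seed, 5L))
    fatigue_gcn(train_ds, splits$val, graph = graph, arch = arch, control = ctrl)
  })
  report <- stage("evaluate", evaluate_model(model, splits$test))

  stage("write", {
    jsonlite::write_json(
      list(case = case$case_id, classes = case$class_subset, seed = seed,
           n_test = sum(report$confusion),
           accuracy = report$accuracy, sensitivity = report$sensitivity,
           specificity = report$specificity, precision = report$precision,
           kappa = report$kappa, macro_auc = report$roc$macro_auc,
           best_epoch = model$best_epoch, val_accuracy = model$val_accuracy),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(as.data.frame(report$confusion),
                     file.path(out_dir, "confusion.csv"))
    roc_df <- do.call(rbind, lapply(names(report$roc$per_class), function(cl) {
      cbind(class = cl, report$roc$per_class[[cl]])
    }))
    utils::write.csv(roc_df, file.path(out_dir, "roc.csv"), row.names = FALSE)
    utils::write.csv(model$history, file.path(out_dir, "history.csv"), row.names = FALSE)
    yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
    write_graph(graph, file.path(out_dir, "graph"))
  })
  invisible(list(model = model, splits = splits, report = report, out_dir = out_dir))
}
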