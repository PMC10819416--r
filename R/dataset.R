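#' Windowed EEG dataset
#'
#' Container for a set of equal-length multi-channel EEG windows with
#' integer class labels and a provenance table (window id, class, seed,
#' real/synthetic flag).
#'
#' @param data Numeric array `channels x samples x windows`.
#' @param labels Integer class ids, one per window (`NA` for unlabeled).
#' @param fs Sampling rate in Hz.
#' @param channel_labels Optional channel names (10-20 system).
#' @param provenance Optional data.frame with one row per window; a
#'   default with columns `window_id`, `class_id`, `seed`, `synthetic` is
#'   created when missing.
#' @return Object of class `windowed_dataset`.
#' @export
windowed_dataset <- function(data, labels, fs, channel_labels = NULL,
                             provenance = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  n <- dim(data)[3]
  stopifnot(length(labels) == n, fs > 0)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(dim(data)[1]))
  stopifnot(length(channel_labels) == dim(data)[1])
  if (is.null(provenance)) {
    provenance <- data.frame(window_id = seq_len(n), class_id = labels,
                             seed = NA_real_, synthetic = FALSE)
  }
  stopifnot(nrow(provenance) == n)
  structure(list(data = data, labels = as.integer(labels), fs = fs,
                 channel_labels = channel_labels, provenance = provenance),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat("<windowed_dataset> ", d[3], " windows, ", d[1], " channels x ", d[2],
      " samples @ ", x$fs, " Hz\n", sep = "")
  if (any(!is.na(x$labels))) {
    tab <- table(x$labels)
    cat("  labels:", paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
  }
  if (any(x$provenance$synthetic)) {
    cat("  synthetic windows:", sum(x$provenance$synthetic), "\n")
  }
  invisible(x)
}

#' Number of windows in a dataset
#' @param ds A [windowed_dataset].
#' @return Integer count.
#' @export
n_windows <- function(ds) dim(ds$data)[3]

#' Subset a windowed dataset
#'
#' @param ds A [windowed_dataset].
#' @param idx Window indices to keep (provenance rows travel along).
#' @return A [windowed_dataset].
#' @export
subset_windows <- function(ds, idx) {
  stopifnot(inherits(ds, "windowed_dataset"))
  windowed_dataset(ds$data[, , idx, drop = FALSE], ds$labels[idx], ds$fs,
                   ds$channel_labels, ds$provenance[idx, , drop = FALSE])
}

#' Concatenate windowed datasets
#'
#' @param ... [windowed_dataset] objects sharing channel count, window
#'   length and sampling rate.
#' @return A [windowed_dataset].
#' @export
bind_windows <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1, all(vapply(parts, inherits, TRUE, "windowed_dataset")))
  d1 <- dim(parts[[1]]$data)[1:2]
  fs <- parts[[1]]$fs
  for (p in parts) stopifnot(all(dim(p$data)[1:2] == d1), p$fs == fs)
  data <- array(0, c(d1, sum(vapply(parts, n_windows, 0L))))
  at <- 0L
  for (p in parts) {
    data[, , at + seq_len(n_windows(p))] <- p$data
    at <- at + n_windows(p)
  }
  prov <- do.call(rbind, lapply(parts, `[[`, "provenance"))
  rownames(prov) <- NULL
  windowed_dataset(data, unlist(lapply(parts, `[[`, "labels")), fs,
                   parts[[1]]$channel_labels, prov)
}

#' Apply a per-window transform
#'
#' @param ds A [windowed_dataset].
#' @param f Function taking a `channels x samples` matrix (and `...`) and
#'   returning one of the same shape.
#' @param ... Passed to `f`.
#' @return A [windowed_dataset].
#' @export
map_windows <- function(ds, f, ...) {
  stopifnot(inherits(ds, "windowed_dataset"))
  out <- ds
  for (w in seq_len(n_windows(ds))) out$data[, , w] <- f(ds$data[, , w], ...)
  out
}

#' Write a cohort to a directory of CSV files
#'
#' One `window_<id>.csv` per window (rows = channels, columns = samples,
#' no header) plus a `manifest.csv` with columns `window_id`, `class_id`,
#' `seed`, `synthetic`, `file`, and a `header.json` recording sampling
#' rate and channel labels.
#'
#' @param ds A [windowed_dataset].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(ds, dir) {
  stopifnot(inherits(ds, "windowed_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("window_%05d.csv", ds$provenance$window_id)
  for (w in seq_len(n_windows(ds))) {
    utils::write.table(ds$data[, , w], file.path(dir, files[w]), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  manifest <- cbind(ds$provenance, file = files)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(list(fs = ds$fs, channel_labels = ds$channel_labels),
                       file.path(dir, "header.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort_csv()]
#'
#' @param dir Directory containing `manifest.csv`, `header.json` and the
#'   per-window CSV files.
#' @return A [windowed_dataset].
#' @export
read_cohort_csv <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  header <- jsonlite::read_json(file.path(dir, "header.json"), simplifyVector = TRUE)
  first <- as.matrix(utils::read.csv(file.path(dir, manifest$file[1]), header = FALSE))
  data <- array(0, c(nrow(first), ncol(first), nrow(manifest)))
  for (w in seq_len(nrow(manifest))) {
    data[, , w] <- as.matrix(utils::read.csv(file.path(dir, manifest$file[w]),
                                             header = FALSE))
  }
  windowed_dataset(data, manifest$class_id, fs = header$fs,
                   channel_labels = header$channel_labels,
                   provenance = manifest[, c("window_id", "class_id", "seed", "synthetic")])
}
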