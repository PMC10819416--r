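#' Confusion matrix
#'
#' @param y_true,y_pred Equal-length label vectors with values in
#'   `levels` (default `0:(K-1)` when `K` is given, otherwise the sorted
#'   union of observed labels).
#' @param K Number of classes (optional when `levels` given).
#' @param levels Explicit class labels in row/column order.
#' @return `K x K` integer matrix, rows = true class, columns =
#'   predicted class, dimnames = labels.
#' @export
confusion_matrix <- function(y_true, y_pred, K = NULL, levels = NULL) {
  stopifnot(length(y_true) == length(y_pred))
  if (is.null(levels)) {
    levels <- if (!is.null(K)) 0:(K - 1) else sort(unique(c(y_true, y_pred)))
  }
  i <- match(y_true, levels)
  j <- match(y_pred, levels)
  if (anyNA(i) || anyNA(j)) stop("label outside the declared class set")
  k <- length(levels)
  cm <- matrix(tabulate((j - 1) * k + i, nbins = k * k), k, k)
  dimnames(cm) <- list(true = levels, predicted = levels)
  cm
}

# Cohen's kappa from a confusion matrix: (p_o - p_e) / (1 - p_e).
kappa_from_cm <- function(cm) {
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

#' Classification metrics from a confusion matrix
#'
#' Binary case (positive = second class): accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, plus Cohen's kappa.
#' Multiclass: one-vs-rest per class, macro-averaged; classes with a
#' zero denominator are flagged undefined and excluded from the macro
#' average with a warning.
#'
#' @param cm Square count matrix (rows = true, columns = predicted),
#'   `sum(cm) > 0`.
#' @return Object of class `metrics_report`: list with `confusion`,
#'   `accuracy`, `sensitivity`, `specificity`, `precision`, `kappa`, and
#'   `per_class` (the one-vs-rest table).
#' @export
metrics_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  k <- nrow(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- n - tp - fn - fp
  safe <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  per_class <- data.frame(class = if (!is.null(rownames(cm))) rownames(cm) else seq_len(k) - 1,
                          TP = tp, TN = tn, FP = fp, FN = fn,
                          sensitivity = safe(tp, tp + fn),
                          specificity = safe(tn, tn + fp),
                          precision = safe(tp, tp + fp))
  macro <- function(v, what) {
    if (anyNA(v)) {
      warning("undefined ", what, " for class(es) ",
              paste(per_class$class[is.na(v)], collapse = ", "),
              "; excluded from the macro average")
    }
    mean(v, na.rm = TRUE)
  }
  if (k == 2) {
    # positive class = second (the more fatigued one)
    res <- list(accuracy = sum(diag(cm)) / n,
                sensitivity = per_class$sensitivity[2],
                specificity = per_class$specificity[2],
                precision = per_class$precision[2])
  } else {
    res <- list(accuracy = sum(diag(cm)) / n,
                sensitivity = macro(per_class$sensitivity, "sensitivity"),
                specificity = macro(per_class$specificity, "specificity"),
                precision = macro(per_class$precision, "precision"))
  }
  structure(c(list(confusion = cm), res,
              list(kappa = kappa_from_cm(cm), per_class = per_class)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> n =", sum(x$confusion), "\n")
  cat(sprintf("  accuracy %.4f  sensitivity %.4f  specificity %.4f  precision %.4f  kappa %.4f\n",
              x$accuracy, x$sensitivity, x$specificity, x$precision, x$kappa))
  invisible(x)
}

#' One-vs-rest ROC curves and AUC
#'
#' Threshold sweep over each class's score column; AUC by the trapezoid
#' rule. Perfectly separating scores give AUC 1, label-independent
#' scores about 0.5.
#'
#' @param y_true Label vector (at least two distinct labels).
#' @param scores `n x K` matrix of per-class scores/probabilities with
#'   class labels as column names (columns matched to
#'   `sort(unique(y_true))` when unnamed).
#' @return List with `per_class` (one data.frame of `threshold`, `fpr`,
#'   `tpr` per class), `auc` (named vector) and `macro_auc`.
#' @export
roc_points <- function(y_true, scores) {
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == length(y_true))
  classes <- sort(unique(y_true))
  if (length(classes) < 2) stop("ROC undefined for single-class labels")
  cls_names <- colnames(scores)
  if (is.null(cls_names)) {
    if (ncol(scores) != length(classes)) {
      stop("unnamed score columns must match the observed classes")
    }
    cls_names <- as.character(classes)
    colnames(scores) <- cls_names
  }
  per_class <- list()
  auc <- numeric(0)
  for (cl in classes) {
    s <- scores[, as.character(cl)]
    pos <- y_true == cl
    np <- sum(pos); nn <- sum(!pos)
    if (np == 0 || nn == 0) {
      warning("class ", cl, " has no positives or no negatives; AUC undefined")
      next
    }
    ord <- order(s, decreasing = TRUE)
    tps <- cumsum(pos[ord]); fps <- cumsum(!pos[ord])
    keep <- c(diff(s[ord]) != 0, TRUE)       # collapse tied thresholds
    tpr <- c(0, tps[keep] / np)
    fpr <- c(0, fps[keep] / nn)
    thr <- c(Inf, s[ord][keep])
    per_class[[as.character(cl)]] <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
    auc[as.character(cl)] <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  }
  list(per_class = per_class, auc = auc, macro_auc = mean(auc))
}

#' Classification case definitions
#'
#' The four nested practical cases over the five ordinal fatigue
#' classes: case I is normal vs full-fatigue; each subsequent case adds
#' the next fatigue stage, up to all five classes in case IV
#' (I = \{0, 4\}, II = \{0, 3, 4\}, III = \{0, 2, 3, 4\},
#' IV = \{0, 1, 2, 3, 4\}).
#'
#' @param case_id One of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @return List of class `case_definition` with `case_id` and
#'   `class_subset` (ordered class ids).
#' @export
define_case <- function(case_id) {
  subsets <- list(I = c(0L, 4L), II = c(0L, 3L, 4L), III = c(0L, 2L, 3L, 4L),
                  IV = 0:4)
  if (!case_id %in% names(subsets)) {
    stop("unknown case '", case_id, "'; expected I, II, III or IV")
  }
  structure(list(case_id = case_id, class_subset = subsets[[case_id]]),
            class = "case_definition")
}

#' Restrict a dataset to a classification case
#'
#' @param ds A labeled [windowed_dataset].
#' @param case A [define_case()] result or case id string.
#' @return A [windowed_dataset] containing only the case's classes.
#' @export
subset_case <- function(ds, case) {
  if (is.character(case)) case <- define_case(case)
  subset_windows(ds, which(ds$labels %in% case$class_subset))
}

#' Evaluate a fitted classifier on a labeled dataset
#'
#' @param model A trained `fatigue_gcn` (or any object with a `predict`
#'   method returning labels and, with `type = "prob"`, probabilities).
#' @param ds A labeled [windowed_dataset].
#' @param roc Also compute one-vs-rest ROC curves (default TRUE).
#' @return A [metrics_from_confusion()] report, with `roc` attached.
#' @export
evaluate_model <- function(model, ds, roc = TRUE) {
  pred <- predict(model, ds)
  levels <- sort(unique(c(ds$labels, pred)))
  rep <- metrics_from_confusion(confusion_matrix(ds$labels, pred, levels = levels))
  if (roc) {
    probs <- predict(model, ds, type = "prob")
    rep$roc <- roc_points(ds$labels, probs)
  }
  rep
}
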