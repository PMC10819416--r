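#' Functional-connectivity adjacency from windows
#'
#' Absolute Pearson correlation between channels, pooled over the
#' provided windows (concatenated along time). Estimate this on the
#' training split only and freeze it for validation/test to avoid
#' leakage. The diagonal is set to zero; negative coupling counts as
#' connectivity via the absolute value.
#'
#' @param ds A [windowed_dataset] (>= 2 channels, each non-constant).
#' @return `n x n` symmetric matrix with zero diagonal, entries in
#'   `[0, 1]`.
#' @export
correlation_adjacency <- function(ds) {
  stopifnot(inherits(ds, "windowed_dataset"))
  d <- dim(ds$data)
  if (d[1] < 2) stop("need at least 2 channels")
  flat <- matrix(aperm(ds$data, c(2, 3, 1)), d[2] * d[3], d[1])
  sds <- apply(flat, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant channel(s): ", paste(ds$channel_labels[sds == 0], collapse = ", "))
  }
  A <- abs(stats::cor(flat))
  diag(A) <- 0
  dimnames(A) <- list(ds$channel_labels, ds$channel_labels)
  A
}

#' Threshold-sparsify an adjacency matrix
#'
#' Zeroes entries strictly below `threshold`; surviving weights are kept
#' (set `binarize = TRUE` for a 0/1 graph).
#'
#' @param A Symmetric matrix with entries in `[0, 1]`.
#' @param threshold Correlation cutoff in `[0, 1]`.
#' @param binarize Replace surviving weights by 1.
#' @return Sparsified matrix, symmetry preserved.
#' @export
sparsify <- function(A, threshold, binarize = FALSE) {
  stopifnot(is.matrix(A), isTRUE(all.equal(A, t(A))))
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  if (any(A < 0 | A > 1)) stop("adjacency entries must lie in [0, 1]")
  A[A < threshold] <- 0
  if (binarize) A[A > 0] <- 1
  A
}

#' Symmetric normalized graph Laplacian
#'
#' `L = I - D^{-1/2} A D^{-1/2}` with `D` the degree matrix. Isolated
#' (degree-0) nodes contribute identity rows, so the edgeless graph gives
#' `L = I`. Eigenvalues lie in `[0, 2]`.
#'
#' @param A Symmetric non-negative adjacency with zero diagonal.
#' @return `n x n` symmetric positive semi-definite matrix.
#' @export
normalized_laplacian <- function(A) {
  stopifnot(is.matrix(A), isTRUE(all.equal(A, t(A))))
  if (any(A < 0)) stop("adjacency entries must be non-negative")
  deg <- rowSums(A)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  L <- diag(nrow(A)) - (dinv %o% dinv) * A
  # isolated nodes: row/col already identity since A row is zero
  (L + t(L)) / 2
}

#' Rescale a Laplacian to the Chebyshev domain
#'
#' `L_tilde = (2 / lambda_max) L - I`, mapping the spectrum into
#' `[-1, 1]` as the Chebyshev recursion requires. `mode = "exact"`
#' computes the top eigenvalue (trivial at 4 nodes); `mode = "approx"`
#' uses the upper bound `lambda_max = 2`.
#'
#' @param L Symmetric PSD matrix.
#' @param mode `"exact"` or `"approx"`.
#' @return List with `L_scaled` and `lambda_max`.
#' @export
scaled_laplacian <- function(L, mode = c("exact", "approx")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(L), isTRUE(all.equal(L, t(L))))
  lambda_max <- if (mode == "exact") max(eigen(L, symmetric = TRUE, only.values = TRUE)$values) else 2
  if (lambda_max <= 0) stop("lambda_max is zero: null Laplacian cannot be rescaled")
  list(L_scaled = (2 / lambda_max) * L - diag(nrow(L)), lambda_max = lambda_max)
}

#' Chebyshev polynomial basis applied to node features
#'
#' Computes `[T_0(L)X, ..., T_{K-1}(L)X]` by the stable three-term
#' recursion `T_k = 2 L T_{k-1} - T_{k-2}` with `T_0 X = X`,
#' `T_1 X = L X`. This is the spectral-filter expansion the graph
#' convolution layers use; `K` is the Chebyshev order (hop radius).
#'
#' @param L_scaled Rescaled Laplacian (`nodes x nodes`, spectrum in
#'   `[-1, 1]`).
#' @param X `nodes x features` matrix.
#' @param K Expansion order, `>= 1`.
#' @return List of `K` matrices shaped like `X`.
#' @export
chebyshev_basis <- function(L_scaled, X, K) {
  if (K < 1) stop("K must be >= 1")
  X <- as.matrix(X)
  stopifnot(is.matrix(L_scaled), nrow(L_scaled) == ncol(L_scaled),
            nrow(X) == nrow(L_scaled))
  out <- vector("list", K)
  out[[1]] <- X
  if (K >= 2) out[[2]] <- L_scaled %*% X
  if (K >= 3) {
    for (k in 3:K) out[[k]] <- 2 * (L_scaled %*% out[[k - 1]]) - out[[k - 2]]
  }
  out
}

# Connectivity check by breadth-first search on the nonzero pattern.
graph_is_connected <- function(A) {
  n <- nrow(A)
  seen <- logical(n)
  frontier <- 1L
  seen[1] <- TRUE
  while (length(frontier)) {
    nxt <- which(colSums(A[frontier, , drop = FALSE] != 0) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Build a channel graph
#'
#' Constructs the full spectral machinery from windows or a precomputed
#' adjacency: absolute-correlation adjacency, threshold sparsification,
#' symmetric normalized Laplacian, and the rescaled Laplacian with its
#' top eigenvalue. Warns when the sparsified graph is disconnected
#' (including edgeless) — the classifier still runs, with isolated nodes
#' filtered independently.
#'
#' @param x A [windowed_dataset] (training split) or an adjacency matrix.
#' @param threshold Sparsification cutoff on `|r|` (default 0.5).
#' @param binarize Binarize surviving edges (default FALSE, weights
#'   kept).
#' @param lambda_max_mode `"exact"` or `"approx"` (see
#'   [scaled_laplacian()]).
#' @return Object of class `channel_graph` with fields `adjacency`,
#'   `threshold`, `degree`, `laplacian_norm`, `laplacian_scaled`,
#'   `lambda_max`, `channel_labels`.
#' @export
channel_graph <- function(x, threshold = 0.5, binarize = FALSE,
                          lambda_max_mode = "exact") {
  if (inherits(x, "windowed_dataset")) {
    A <- correlation_adjacency(x)
    labels <- x$channel_labels
  } else {
    A <- as.matrix(x)
    labels <- rownames(A)
    if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(A)))
  }
  A <- sparsify(A, threshold, binarize = binarize)
  if (!graph_is_connected(A)) {
    warning("sparsified channel graph is disconnected at threshold ", threshold)
  }
  L <- normalized_laplacian(A)
  sc <- scaled_laplacian(L, mode = lambda_max_mode)
  structure(list(adjacency = A, threshold = threshold,
                 degree = diag(rowSums(A), nrow(A)),
                 laplacian_norm = L, laplacian_scaled = sc$L_scaled,
                 lambda_max = sc$lambda_max, channel_labels = labels),
            class = "channel_graph")
}

#' @export
print.channel_graph <- function(x, ...) {
  n <- nrow(x$adjacency)
  cat("<channel_graph> ", n, " nodes (", paste(x$channel_labels, collapse = ", "),
      "), ", sum(x$adjacency[upper.tri(x$adjacency)] != 0), " edges, threshold ",
      x$threshold, ", lambda_max ", signif(x$lambda_max, 4), "\n", sep = "")
  invisible(x)
}

#' Export a channel graph as edge list + JSON header
#'
#' Writes `edges.csv` (columns `i`, `j`, `weight`, upper triangle) and
#' `graph.json` (threshold, lambda_max, channel labels).
#'
#' @param graph A [channel_graph].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_graph <- function(graph, dir) {
  stopifnot(inherits(graph, "channel_graph"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ut <- which(upper.tri(graph$adjacency) & graph$adjacency != 0, arr.ind = TRUE)
  edges <- data.frame(i = ut[, 1], j = ut[, 2], weight = graph$adjacency[ut])
  utils::write.csv(edges, file.path(dir, "edges.csv"), row.names = FALSE)
  jsonlite::write_json(list(threshold = graph$threshold, lambda_max = graph$lambda_max,
                            n_nodes = nrow(graph$adjacency),
                            channel_labels = graph$channel_labels),
                       file.path(dir, "graph.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a channel graph written by [write_graph()]
#'
#' @param dir Directory containing `edges.csv` and `graph.json`.
#' @return A [channel_graph].
#' @export
read_graph <- function(dir) {
  header <- jsonlite::read_json(file.path(dir, "graph.json"), simplifyVector = TRUE)
  edges <- utils::read.csv(file.path(dir, "edges.csv"))
  A <- matrix(0, header$n_nodes, header$n_nodes)
  if (nrow(edges)) {
    A[cbind(edges$i, edges$j)] <- edges$weight
    A[cbind(edges$j, edges$i)] <- edges$weight
  }
  dimnames(A) <- list(header$channel_labels, header$channel_labels)
  channel_graph(A, threshold = header$threshold)
}
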