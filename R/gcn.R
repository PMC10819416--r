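#' Graph-convolution layer specification
#'
#' One Chebyshev graph-convolution layer: a spectral filter of order
#' `cheb_order` mapping `in_features` to `out_features` per node,
#' followed by Leaky-ReLU and batch normalization. The weight tensor has
#' exactly `cheb_order * in_features * out_features` elements and the
#' bias `out_features`.
#'
#' @param cheb_order Chebyshev expansion order `C_k >= 1`.
#' @param in_features,out_features Per-node feature widths (`>= 1`).
#' @param leaky_slope Leaky-ReLU negative slope (default 0.01).
#' @param batch_norm Attach batch normalization (default TRUE).
#' @return Object of class `layer_spec`.
#' @export
layer_spec <- function(cheb_order, in_features, out_features,
                       leaky_slope = 0.01, batch_norm = TRUE) {
  stopifnot(cheb_order >= 1, in_features >= 1, out_features >= 1)
  structure(list(cheb_order = as.integer(cheb_order),
                 in_features = as.integer(in_features),
                 out_features = as.integer(out_features),
                 leaky_slope = leaky_slope, batch_norm = batch_norm),
            class = "layer_spec")
}

#' Classifier architecture specification
#'
#' Stack of Chebyshev graph-convolution layers over a fixed node set
#' (feature widths shrink along the chain; the node count never
#' changes), then dropout, flattening, and a fully connected softmax
#' head. The default is the width-replica chain
#' 2920 -> 2920 -> 1460 -> 730 -> 365 -> 180 on 4 nodes with 4 output
#' classes, whose parameter table [count_parameters()] reproduces
#' analytically.
#'
#' @param feature_chain Per-node widths, input first (length
#'   `n_layers + 1`).
#' @param cheb_orders Chebyshev order per layer (default all 1, the
#'   accuracy-maximizing setting).
#' @param n_nodes Graph nodes = channels (default 4).
#' @param n_classes Output classes (default 4).
#' @param dropout_rate Dropout after the last conv layer (default 0.3).
#' @param leaky_slope Leaky-ReLU negative slope (default 0.01).
#' @return Object of class `architecture_spec` with a `layers` list of
#'   [layer_spec] and `flatten_dim = n_nodes * last width`.
#' @export
architecture_spec <- function(feature_chain = c(2920L, 2920L, 1460L, 730L, 365L, 180L),
                              cheb_orders = rep(1L, length(feature_chain) - 1L),
                              n_nodes = 4L, n_classes = 4L, dropout_rate = 0.3,
                              leaky_slope = 0.01) {
  n_layers <- length(feature_chain) - 1L
  # n_classes = 0 marks a headless (degenerate) spec used only for
  # parameter accounting.
  stopifnot(n_layers >= 0, length(cheb_orders) == n_layers,
            all(feature_chain >= 1), n_nodes >= 1, n_classes == 0 || n_classes >= 2,
            dropout_rate >= 0, dropout_rate < 1)
  layers <- lapply(seq_len(n_layers), function(l) {
    layer_spec(cheb_orders[l], feature_chain[l], feature_chain[l + 1],
               leaky_slope = leaky_slope)
  })
  flatten_dim <- as.integer(n_nodes * feature_chain[length(feature_chain)])
  structure(list(layers = layers, n_nodes = as.integer(n_nodes),
                 n_classes = as.integer(n_classes), dropout_rate = dropout_rate,
                 flatten_dim = flatten_dim,
                 feature_chain = as.integer(feature_chain),
                 cheb_orders = as.integer(cheb_orders)),
            class = "architecture_spec")
}

#' Reduced architecture for desk-scale runs
#'
#' Five-layer replica of the default chain scaled to 64-sample node
#' features: 64 -> 64 -> 32 -> 16 -> 8 -> 8 (first layer
#' width-preserving, then halvings, like the full-width default),
#' Chebyshev order 1 throughout.
#'
#' @param n_classes Output classes.
#' @param ... Passed to [architecture_spec()].
#' @return An [architecture_spec].
#' @export
smoke_architecture <- function(n_classes = 2L, ...) {
  architecture_spec(feature_chain = c(64L, 64L, 32L, 16L, 8L, 8L),
                    n_classes = n_classes, ...)
}

#' Analytic parameter accounting
#'
#' Per-layer table of trainable parameter counts: each graph-conv layer
#' contributes `cheb_order * in * out` weights (`in * out` per Chebyshev
#' order), `out` biases and `2 * out` batch-norm parameters; the fully
#' connected head contributes `flatten_dim * n_classes` weights and
#' `n_classes` biases. Matches a brute-force enumeration of the arrays a
#' built model instantiates.
#'
#' @param spec An [architecture_spec].
#' @return data.frame with columns `layer`, `cheb_order`,
#'   `weights_per_order`, `weights`, `bias`, `batch_norm`, `total`, plus
#'   attributes `flatten_dim` and `grand_total`.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  rows <- lapply(seq_along(spec$layers), function(l) {
    ls <- spec$layers[[l]]
    wpo <- as.double(ls$in_features) * ls$out_features
    w <- wpo * ls$cheb_order
    bn <- if (ls$batch_norm) 2 * ls$out_features else 0
    data.frame(layer = paste0("conv", l), cheb_order = ls$cheb_order,
               weights_per_order = wpo, weights = w, bias = ls$out_features,
               batch_norm = bn, total = w + ls$out_features + bn)
  })
  if (spec$n_classes > 0) {
    fc_w <- as.double(spec$flatten_dim) * spec$n_classes
    rows <- c(rows, list(data.frame(layer = "fc", cheb_order = NA_integer_,
                                    weights_per_order = NA_real_, weights = fc_w,
                                    bias = spec$n_classes, batch_norm = 0,
                                    total = fc_w + spec$n_classes)))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(layer = character(0), cheb_order = integer(0),
               weights_per_order = numeric(0), weights = numeric(0),
               bias = numeric(0), batch_norm = numeric(0), total = numeric(0))
  attr(out, "flatten_dim") <- spec$flatten_dim
  attr(out, "grand_total") <- sum(out$total)
  out
}

#' Training configuration for the classifier
#'
#' Defaults follow the tuned values: Adamax with learning rate 1e-4,
#' weight decay 4e-4, batch size 16, cross-entropy loss, 150 epochs.
#'
#' @param epochs Training epochs.
#' @param learning_rate Adamax learning rate.
#' @param weight_decay L2 weight decay applied to weight matrices.
#' @param batch_size Minibatch size.
#' @param seed Integer seed.
#' @return Object of class `gcn_control`.
#' @export
gcn_control <- function(epochs = 150L, learning_rate = 1e-4, weight_decay = 4e-4,
                        batch_size = 16L, seed = 1L) {
  stopifnot(epochs >= 1, learning_rate > 0, weight_decay >= 0, batch_size >= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 optimizer = "adamax", loss = "cross-entropy",
                 seed = as.integer(seed)),
            class = "gcn_control")
}

# Precompute T_k(L_scaled) matrices up to the maximum order in the spec.
cheb_matrices <- function(L_scaled, K) {
  n <- nrow(L_scaled)
  Tk <- vector("list", K)
  Tk[[1]] <- diag(n)
  if (K >= 2) Tk[[2]] <- L_scaled
  if (K >= 3) for (k in 3:K) Tk[[k]] <- 2 * L_scaled %*% Tk[[k - 1]] - Tk[[k - 2]]
  Tk
}

#' Build an untrained Chebyshev GCN classifier
#'
#' @param arch An [architecture_spec].
#' @param graph A [channel_graph] with `arch$n_nodes` nodes.
#' @param seed Integer seed for weight initialization.
#' @param init First-layer initialization. `"spectral"` (default) fills
#'   the first layer's order-0 block with quadrature sinusoidal probes —
#'   evenly spaced frequencies, four phases each — so the network starts
#'   from frequency-selective projections of the oscillatory node
#'   features (rectified by Leaky-ReLU, these give the deeper layers
#'   direct access to band envelopes); `"glorot"` is plain uniform
#'   Glorot everywhere.
#' @return Object of class `fatigue_gcn` (untrained).
#' @export
build_gcn <- function(arch, graph, seed = 1L, init = c("spectral", "glorot")) {
  init <- match.arg(init)
  stopifnot(inherits(arch, "architecture_spec"), inherits(graph, "channel_graph"))
  if (arch$n_classes < 2) stop("architecture must have at least 2 output classes")
  if (nrow(graph$adjacency) != arch$n_nodes) {
    stop("graph has ", nrow(graph$adjacency), " nodes but architecture expects ",
         arch$n_nodes)
  }
  maxK <- max(c(1L, arch$cheb_orders))
  Tk <- cheb_matrices(graph$laplacian_scaled, maxK)
  local_seed(seed, {
    params <- list()
    bn_state <- list()
    for (l in seq_along(arch$layers)) {
      ls <- arch$layers[[l]]
      params[[paste0("W", l)]] <- glorot(ls$cheb_order * ls$in_features,
                                         ls$out_features,
                                         c(ls$in_features, ls$out_features, ls$cheb_order))
      params[[paste0("b", l)]] <- numeric(ls$out_features)
      if (ls$batch_norm) {
        params[[paste0("gamma", l)]] <- rep(1, ls$out_features)
        params[[paste0("beta", l)]] <- numeric(ls$out_features)
        bn_state[[l]] <- list(mean = numeric(ls$out_features),
                              var = rep(1, ls$out_features))
      }
    }
    params$Wfc <- glorot(arch$flatten_dim, arch$n_classes,
                         c(arch$flatten_dim, arch$n_classes))
    params$bfc <- numeric(arch$n_classes)
    if (init == "spectral" && length(arch$layers) > 0) {
      L0 <- arch$layers[[1]]$in_features
      F1 <- arch$layers[[1]]$out_features
      tt <- (seq_len(L0) - 1) / L0           # window-relative time
      n_freq <- ceiling(F1 / 4)
      freqs <- seq(1, max(1, L0 / 2 * 0.8), length.out = n_freq)  # cycles/window
      probes <- matrix(0, L0, F1)
      j <- 1L
      for (f in freqs) {
        for (ph in c(0, pi / 2, pi, 3 * pi / 2)) {
          if (j <= F1) probes[, j] <- sin(2 * pi * f * tt + ph)
          j <- j + 1L
        }
      }
      params$W1[, , 1] <- probes * sqrt(2 / L0)
    }
    structure(list(arch = arch, graph = graph, params = params,
                   bn_state = bn_state, Tk = Tk, classes = NULL,
                   history = NULL, trained = FALSE),
              class = "fatigue_gcn")
  })
}

# Forward pass. X: n_nodes x F0 x B array. training toggles batch-norm
# batch statistics and dropout. Returns logits (B x K) and caches.
gcn_forward <- function(model, X, training = FALSE, update_bn = training) {
  arch <- model$arch
  p <- model$params
  n <- arch$n_nodes
  B <- dim(X)[3]
  eps <- 1e-5
  caches <- vector("list", length(arch$layers))
  bn_state <- model$bn_state
  H <- X
  for (l in seq_along(arch$layers)) {
    ls <- arch$layers[[l]]
    K <- ls$cheb_order
    W <- p[[paste0("W", l)]]
    Fin <- ls$in_features; Fout <- ls$out_features
    Hmat <- matrix(H, n, Fin * B)
    Y <- matrix(0, n * B, Fout)
    TXs <- vector("list", K)
    for (k in seq_len(K)) {
      TX <- array(model$Tk[[k]] %*% Hmat, c(n, Fin, B))
      M <- matrix(aperm(TX, c(1, 3, 2)), n * B, Fin)
      TXs[[k]] <- M
      Y <- Y + M %*% W[, , k]
    }
    Y <- sweep(Y, 2, p[[paste0("b", l)]], `+`)      # (n*B) x Fout
    act <- lrelu(Y, ls$leaky_slope)
    if (ls$batch_norm) {
      if (training) {
        mu <- colMeans(act)
        v <- colMeans(sweep(act, 2, mu)^2)
        if (update_bn) {
          bn_state[[l]]$mean <- 0.9 * bn_state[[l]]$mean + 0.1 * mu
          bn_state[[l]]$var <- 0.9 * bn_state[[l]]$var + 0.1 * v
        }
      } else {
        mu <- bn_state[[l]]$mean
        v <- bn_state[[l]]$var
      }
      xhat <- sweep(sweep(act, 2, mu), 2, sqrt(v + eps), `/`)
      out <- sweep(sweep(xhat, 2, p[[paste0("gamma", l)]], `*`), 2,
                   p[[paste0("beta", l)]], `+`)
    } else {
      xhat <- NULL; mu <- NULL; v <- NULL
      out <- act
    }
    caches[[l]] <- list(TXs = TXs, Y = Y, act = act, xhat = xhat, mu = mu, v = v)
    H <- aperm(array(out, c(n, B, Fout)), c(1, 3, 2))
  }
  # dropout -> flatten -> fc
  flat <- matrix(H, n * dim(H)[2], B)               # flatten_dim x B
  drop_mask <- NULL
  if (training && arch$dropout_rate > 0) {
    drop_mask <- matrix(stats::rbinom(length(flat), 1, 1 - arch$dropout_rate),
                        nrow(flat)) / (1 - arch$dropout_rate)
    flat <- flat * drop_mask
  }
  logits <- dense_fwd(t(flat), p$Wfc, p$bfc)
  list(logits = logits, caches = caches, flat = flat, drop_mask = drop_mask,
       bn_state = bn_state, B = B)
}

# Backward pass given dlogits (B x K); returns gradient list.
gcn_backward <- function(model, X, fwd, dlogits) {
  arch <- model$arch
  p <- model$params
  n <- arch$n_nodes
  B <- fwd$B
  eps <- 1e-5
  grads <- list()
  gfc <- dense_bwd(t(fwd$flat), p$Wfc, dlogits)
  grads$Wfc <- gfc$dW; grads$bfc <- gfc$db
  dflat <- t(gfc$dX)                                  # flatten_dim x B
  if (!is.null(fwd$drop_mask)) dflat <- dflat * fwd$drop_mask
  Flast <- arch$layers[[length(arch$layers)]]$out_features
  dH <- aperm(array(dflat, c(n, Flast, B)), c(1, 2, 3)) # n x Fout x B
  for (l in rev(seq_along(arch$layers))) {
    ls <- arch$layers[[l]]
    K <- ls$cheb_order
    Fin <- ls$in_features; Fout <- ls$out_features
    cc <- fwd$caches[[l]]
    dOut <- matrix(aperm(dH, c(1, 3, 2)), n * B, Fout)
    if (ls$batch_norm) {
      m <- n * B
      gamma <- p[[paste0("gamma", l)]]
      grads[[paste0("gamma", l)]] <- colSums(dOut * cc$xhat)
      grads[[paste0("beta", l)]] <- colSums(dOut)
      dxhat <- sweep(dOut, 2, gamma, `*`)
      istd <- 1 / sqrt(cc$v + eps)
      xc <- sweep(cc$act, 2, cc$mu)
      dvar <- colSums(dxhat * xc) * (-0.5) * istd^3
      dmu <- colSums(sweep(dxhat, 2, -istd, `*`)) + dvar * (-2) * colMeans(xc)
      dact <- sweep(dxhat, 2, istd, `*`) +
        sweep(xc, 2, 2 * dvar / m, `*`) +
        matrix(dmu / m, m, Fout, byrow = TRUE)
    } else {
      dact <- dOut
    }
    dY <- dact * lrelu_grad(cc$Y, ls$leaky_slope)
    W <- p[[paste0("W", l)]]
    dW <- array(0, dim(W))
    dM_total <- NULL
    grads[[paste0("b", l)]] <- colSums(dY)
    dHmat <- matrix(0, n, Fin * B)
    for (k in seq_len(K)) {
      M <- cc$TXs[[k]]
      dW[, , k] <- t(M) %*% dY
      dM <- dY %*% t(W[, , k])                        # (n*B) x Fin
      dTX <- aperm(array(dM, c(n, B, Fin)), c(1, 3, 2))
      dHmat <- dHmat + t(model$Tk[[k]]) %*% matrix(dTX, n, Fin * B)
    }
    grads[[paste0("W", l)]] <- dW
    dH <- array(dHmat, c(n, Fin, B))
  }
  grads
}

# Accuracy + mean loss of a model on a dataset (inference mode).
gcn_evaluate <- function(model, ds) {
  X <- ds$data
  y <- match(ds$labels, model$classes)
  fwd <- gcn_forward(model, X, training = FALSE)
  sm <- softmax_xent(fwd$logits, y)
  pred <- max.col(fwd$logits, ties.method = "first")
  list(loss = sm$loss, accuracy = mean(pred == y))
}

#' Stratified train/validation/test split
#'
#' Splits windows per class into train/validation/test with
#' floor-then-largest-remainder counts, so 2920 windows per class give
#' 2044/584/292. The partition is a pure function of the seed and the
#' windows' provenance ids: windows are ordered by `window_id` before
#' shuffling, so a permuted input yields the identical partition.
#'
#' @param ds A labeled [windowed_dataset]; every class needs at least 3
#'   windows.
#' @param fractions Length-3 non-negative fractions summing to 1
#'   (default `c(0.7, 0.2, 0.1)`).
#' @param seed Integer seed.
#' @return Named list of [windowed_dataset]: `train`, `val`, `test`.
#' @export
split_dataset <- function(ds, fractions = c(0.7, 0.2, 0.1), seed = 1L) {
  stopifnot(inherits(ds, "windowed_dataset"), length(fractions) == 3,
            all(fractions >= 0), abs(sum(fractions) - 1) < 1e-9)
  classes <- sort(unique(ds$labels))
  take <- list(train = integer(0), val = integer(0), test = integer(0))
  for (cl in classes) {
    idx <- which(ds$labels == cl)
    if (length(idx) < 3) stop("class ", cl, " has fewer than 3 windows")
    idx <- idx[order(ds$provenance$window_id[idx])]
    perm <- local_seed(derive_seed(seed, 3L, cl), sample.int(length(idx)))
    idx <- idx[perm]
    n <- length(idx)
    counts <- floor(fractions * n)
    rem <- n - sum(counts)
    if (rem > 0) {
      extra <- order(fractions * n - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1
    }
    at <- 0
    for (s in 1:3) {
      take[[s]] <- c(take[[s]], idx[at + seq_len(counts[s])])
      at <- at + counts[s]
    }
  }
  lapply(take, function(i) subset_windows(ds, sort(i)))
}

#' Train a Chebyshev GCN classifier
#'
#' Minibatch Adamax training with cross-entropy loss. The weights with
#' the best validation accuracy are retained (ties broken by lower
#' validation loss, then earlier epoch). Weight decay applies to weight
#' matrices only.
#'
#' @param model An untrained [build_gcn()] model.
#' @param train,val Labeled [windowed_dataset] splits (disjoint).
#' @param control A [gcn_control].
#' @return A trained `fatigue_gcn` with per-epoch `history`.
#' @export
train_gcn <- function(model, train, val, control = gcn_control()) {
  stopifnot(inherits(model, "fatigue_gcn"), inherits(train, "windowed_dataset"),
            inherits(val, "windowed_dataset"))
  if (n_windows(train) == 0 || n_windows(val) == 0) stop("empty split")
  classes <- sort(unique(c(train$labels, val$labels)))
  if (length(classes) != model$arch$n_classes) {
    stop("label set has ", length(classes), " classes but architecture expects ",
         model$arch$n_classes)
  }
  if (dim(train$data)[2] != model$arch$feature_chain[1]) {
    stop("window length ", dim(train$data)[2], " does not match input width ",
         model$arch$feature_chain[1])
  }
  model$classes <- classes
  y <- match(train$labels, classes)
  ntr <- n_windows(train)
  decay_mask <- lapply(names(model$params), function(nm) grepl("^W", nm))
  names(decay_mask) <- names(model$params)
  local_seed(control$seed, {
    opt <- adamax_state(model$params, lr = control$learning_rate,
                        weight_decay = control$weight_decay)
    hist <- data.frame(epoch = seq_len(control$epochs), train_loss = NA_real_,
                       train_acc = NA_real_, val_loss = NA_real_, val_acc = NA_real_)
    best <- list(acc = -Inf, loss = Inf, epoch = Inf, params = model$params,
                 bn_state = model$bn_state)
    for (ep in seq_len(control$epochs)) {
      ord <- sample.int(ntr)
      ep_loss <- 0; ep_hits <- 0
      for (start in seq(1, ntr, by = control$batch_size)) {
        bi <- ord[start:min(start + control$batch_size - 1, ntr)]
        X <- train$data[, , bi, drop = FALSE]
        fwd <- gcn_forward(model, X, training = TRUE)
        model$bn_state <- fwd$bn_state
        sm <- softmax_xent(fwd$logits, y[bi])
        if (!is.finite(sm$loss)) stop("non-finite training loss at epoch ", ep)
        grads <- gcn_backward(model, X, fwd, sm$dlogits)
        st <- adamax_step(model$params, grads, opt, decay_mask)
        model$params <- st$params; opt <- st$state
        ep_loss <- ep_loss + sm$loss * length(bi)
        ep_hits <- ep_hits + sum(max.col(fwd$logits, ties.method = "first") == y[bi])
      }
      hist$train_loss[ep] <- ep_loss / ntr
      hist$train_acc[ep] <- ep_hits / ntr
      ev <- gcn_evaluate(model, val)
      hist$val_loss[ep] <- ev$loss
      hist$val_acc[ep] <- ev$accuracy
      if (ev$accuracy > best$acc ||
          (ev$accuracy == best$acc && ev$loss < best$loss)) {
        best <- list(acc = ev$accuracy, loss = ev$loss, epoch = ep,
                     params = model$params, bn_state = model$bn_state)
      }
    }
    model$params <- best$params
    model$bn_state <- best$bn_state
    model$history <- hist
    model$best_epoch <- best$epoch
    model$val_accuracy <- best$acc
    model$control <- control
    model$trained <- TRUE
    model
  })
}

#' Fit a Chebyshev graph-convolutional fatigue classifier
#'
#' The package's main modeling entry point: builds the channel graph
#' from the training split (unless one is supplied), instantiates the
#' architecture, and trains with Adamax/cross-entropy, retaining the
#' best-validation-accuracy weights.
#'
#' @param train,val Labeled [windowed_dataset] splits (normalized
#'   windows).
#' @param graph Optional [channel_graph]; default is estimated from
#'   `train` only (leakage guard).
#' @param arch An [architecture_spec]; its input width must equal the
#'   window length.
#' @param control A [gcn_control].
#' @param graph_threshold Sparsification threshold when the graph is
#'   estimated here.
#' @param init First-layer initialization, see [build_gcn()].
#' @return A trained object of class `fatigue_gcn`; see
#'   [predict.fatigue_gcn()], `print`, `summary`, `plot`.
#' @export
fatigue_gcn <- function(train, val, graph = NULL, arch, control = gcn_control(),
                        graph_threshold = 0.5, init = "spectral") {
  if (is.null(graph)) graph <- channel_graph(train, threshold = graph_threshold)
  model <- build_gcn(arch, graph, seed = derive_seed(control$seed, 1L), init = init)
  train_gcn(model, train, val, control)
}

#' Predict from a fitted fatigue classifier
#'
#' Inference is deterministic: dropout is disabled and batch
#' normalization uses running statistics.
#'
#' @param object A trained `fatigue_gcn`.
#' @param newdata A [windowed_dataset] or `channels x samples x n` array
#'   whose window length matches the architecture input width.
#' @param type `"class"` for labels, `"prob"` for the class-probability
#'   matrix.
#' @param ... Unused.
#' @return Integer class labels, or an `n x n_classes` probability
#'   matrix with class-id column names.
#' @export
predict.fatigue_gcn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (!isTRUE(object$trained)) stop("model is not trained")
  X <- if (inherits(newdata, "windowed_dataset")) newdata$data else newdata
  stopifnot(is.array(X), length(dim(X)) == 3)
  if (dim(X)[2] != object$arch$feature_chain[1]) {
    stop("window length ", dim(X)[2], " does not match model input width ",
         object$arch$feature_chain[1])
  }
  fwd <- gcn_forward(object, X, training = FALSE)
  z <- fwd$logits - apply(fwd$logits, 1, max)
  probs <- exp(z) / rowSums(exp(z))
  colnames(probs) <- object$classes
  if (type == "prob") probs else object$classes[max.col(probs, ties.method = "first")]
}

#' @export
print.fatigue_gcn <- function(x, ...) {
  cat("<fatigue_gcn> ", length(x$arch$layers), " Chebyshev conv layers [",
      paste(x$arch$feature_chain, collapse = " -> "), "] on ", x$arch$n_nodes,
      " nodes, ", x$arch$n_classes, " classes\n", sep = "")
  cat("  Chebyshev orders:", paste(x$arch$cheb_orders, collapse = ", "), "\n")
  if (isTRUE(x$trained)) {
    cat("  trained ", nrow(x$history), " epochs; best epoch ", x$best_epoch,
        ", validation accuracy ", round(x$val_accuracy, 4), "\n", sep = "")
  } else {
    cat("  untrained\n")
  }
  invisible(x)
}

#' @export
summary.fatigue_gcn <- function(object, ...) {
  pt <- count_parameters(object$arch)
  cat("Chebyshev graph-convolutional fatigue classifier\n")
  print(object)
  cat("\nParameter accounting:\n")
  print(pt, row.names = FALSE)
  cat("\nTotal trainable parameters:", format(attr(pt, "grand_total"), big.mark = ","), "\n")
  if (isTRUE(object$trained)) {
    cat("\nFinal epoch: train acc ", round(utils::tail(object$history$train_acc, 1), 4),
        ", val acc ", round(utils::tail(object$history$val_acc, 1), 4), "\n", sep = "")
  }
  invisible(pt)
}

#' Plot training history
#'
#' @param x A trained `fatigue_gcn`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.fatigue_gcn <- function(x, ...) {
  if (is.null(x$history)) stop("no training history to plot")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "l", lty = 1,
                    col = c("steelblue", "firebrick"), xlab = "epoch",
                    ylab = "accuracy", ylim = c(0, 1), ...)
  graphics::legend("bottomright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}
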