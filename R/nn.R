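# Minimal neural-network primitives (forward passes, analytic gradients,
# Adam/Adamax) shared by the GAN augmenter and the Chebyshev GCN. All
# math is plain base-R matrix algebra; shapes are documented per helper.

glorot <- function(fan_in, fan_out, dims) {
  array(stats::runif(prod(dims), -1, 1) * sqrt(6 / (fan_in + fan_out)), dims)
}

lrelu <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)
lrelu_grad <- function(x, slope = 0.01) ifelse(x > 0, 1, slope)
sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- dense layer: X (batch x in) %*% W (in x out) + b --------------------
dense_fwd <- function(X, W, b) sweep(X %*% W, 2, b, `+`)
dense_bwd <- function(X, W, dY) {
  list(dX = dY %*% t(W), dW = t(X) %*% dY, db = colSums(dY))
}

# ---- 1-D convolution, stride 1, same padding -----------------------------
# x: Cin x L ; returns (Cin*k) x L patch matrix (zero padded).
im2col1d <- function(x, k) {
  Cin <- nrow(x); L <- ncol(x); p <- (k - 1L) %/% 2L
  xp <- cbind(matrix(0, Cin, p), x, matrix(0, Cin, p))
  out <- matrix(0, Cin * k, L)
  for (j in seq_len(k)) {
    out[(j - 1L) * Cin + seq_len(Cin), ] <- xp[, j:(j + L - 1L), drop = FALSE]
  }
  out
}

col2im1d <- function(dcol, Cin, L, k) {
  p <- (k - 1L) %/% 2L
  dxp <- matrix(0, Cin, L + 2L * p)
  for (j in seq_len(k)) {
    dxp[, j:(j + L - 1L)] <- dxp[, j:(j + L - 1L)] +
      dcol[(j - 1L) * Cin + seq_len(Cin), , drop = FALSE]
  }
  dxp[, p + seq_len(L), drop = FALSE]
}

# x: Cin x L, W: Cout x (Cin*k), b: Cout -> y: Cout x L (+ cached patches)
conv1d_fwd <- function(x, W, b, k) {
  col <- im2col1d(x, k)
  list(y = W %*% col + b, col = col)
}
conv1d_bwd <- function(cache, W, dY, Cin, L, k) {
  list(dW = dY %*% t(cache$col), db = rowSums(dY),
       dx = col2im1d(t(W) %*% dY, Cin, L, k))
}

# ---- linear upsampling along time ---------------------------------------
# Interpolation matrix U (Lout x Lin): y = x %*% t(U) per channel row.
upsample_matrix <- function(Lin, Lout) {
  if (Lin == 1) return(matrix(1, Lout, 1))
  pos <- seq(0, Lin - 1, length.out = Lout)
  lo <- pmin(floor(pos), Lin - 2)
  frac <- pos - lo
  U <- matrix(0, Lout, Lin)
  U[cbind(seq_len(Lout), lo + 1)] <- 1 - frac
  U[cbind(seq_len(Lout), lo + 2)] <- U[cbind(seq_len(Lout), lo + 2)] + frac
  U
}

# ---- optimizers ----------------------------------------------------------
# params/grads: flat named lists of arrays. State initialized lazily.
adam_state <- function(params, lr = 0.001, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, st) {
  st$t <- st$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- st$beta1 * st$m[[nm]] + (1 - st$beta1) * g
    st$v[[nm]] <- st$beta2 * st$v[[nm]] + (1 - st$beta2) * g^2
    mhat <- st$m[[nm]] / (1 - st$beta1^st$t)
    vhat <- st$v[[nm]] / (1 - st$beta2^st$t)
    params[[nm]] <- params[[nm]] - st$lr * mhat / (sqrt(vhat) + st$eps)
  }
  list(params = params, state = st)
}

# Adamax: infinity-norm variant of Adam.
adamax_state <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, weight_decay = 0) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0,
       weight_decay = weight_decay,
       m = lapply(params, function(p) p * 0),
       u = lapply(params, function(p) p * 0))
}

adamax_step <- function(params, grads, st, decay_mask = NULL) {
  st$t <- st$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (st$weight_decay > 0 && (is.null(decay_mask) || isTRUE(decay_mask[[nm]]))) {
      g <- g + st$weight_decay * params[[nm]]
    }
    st$m[[nm]] <- st$beta1 * st$m[[nm]] + (1 - st$beta1) * g
    st$u[[nm]] <- pmax(st$beta2 * st$u[[nm]], abs(g))
    params[[nm]] <- params[[nm]] -
      (st$lr / (1 - st$beta1^st$t)) * st$m[[nm]] / (st$u[[nm]] + st$eps)
  }
  list(params = params, state = st)
}

# Numerically stable softmax + cross-entropy. logits: batch x K,
# y: integer class index 1..K. Returns loss, probs, dlogits.
softmax_xent <- function(logits, y) {
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  n <- nrow(logits)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y)], 1e-12)))
  d <- p
  d[cbind(seq_len(n), y)] <- d[cbind(seq_len(n), y)] - 1
  list(loss = loss, probs = p, dlogits = d / n)
}

# Binary cross-entropy on sigmoid outputs; returns loss and gradient
# w.r.t. the pre-sigmoid logit (the stable combined form).
bce_logits <- function(logits, target) {
  p <- sigmoid(logits)
  loss <- -mean(target * log(pmax(p, 1e-12)) + (1 - target) * log(pmax(1 - p, 1e-12)))
  list(loss = loss, dlogits = (p - target) / length(logits), probs = p)
}
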