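#' Generator specification
#'
#' Four-stage 1-D convolutional generator: a dense projection of the
#' latent vector to a `n_filters[1] x layer_widths[1]` feature map,
#' followed by three (linear-upsample + 1-D convolution) stages whose
#' sequence lengths follow `layer_widths`, with ReLU activations and a
#' final sigmoid so synthetic windows live in `[0, 1]` like the
#' normalized real windows. The last width must equal the per-channel
#' window length.
#'
#' @param latent_dim Latent dimension (default 100).
#' @param layer_widths Sequence lengths of the four stages (default
#'   `c(128, 256, 512, 1250)`).
#' @param n_channels Output channels (default 4).
#' @param n_filters Feature maps of the first three stages (default
#'   `c(16, 16, 8)`).
#' @param kernel_size Odd convolution kernel length (default 9).
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(latent_dim = 100L, layer_widths = c(128L, 256L, 512L, 1250L),
                           n_channels = 4L, n_filters = c(16L, 16L, 8L),
                           kernel_size = 9L) {
  stopifnot(latent_dim >= 1, length(layer_widths) == 4, all(layer_widths >= 1),
            length(n_filters) == 3, all(n_filters >= 1),
            kernel_size %% 2 == 1)
  structure(list(latent_dim = as.integer(latent_dim),
                 layer_widths = as.integer(layer_widths),
                 n_channels = as.integer(n_channels),
                 n_filters = as.integer(n_filters),
                 kernel_size = as.integer(kernel_size), activation = "relu"),
            class = "generator_spec")
}

#' Discriminator specification
#'
#' Four fully connected layers with Leaky-ReLU activations, dropout on
#' the first layer ("random elimination"), and a sigmoid real/fake
#' output.
#'
#' @param layer_widths Widths of the four layers (default
#'   `c(512, 256, 128, 1)`; the last must be 1).
#' @param dropout_rate_first_layer Dropout fraction after the first layer
#'   (default 0.3).
#' @return Object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(layer_widths = c(512L, 256L, 128L, 1L),
                               dropout_rate_first_layer = 0.3) {
  stopifnot(length(layer_widths) == 4, all(layer_widths >= 1),
            layer_widths[4] == 1,
            dropout_rate_first_layer >= 0, dropout_rate_first_layer < 1)
  structure(list(layer_widths = as.integer(layer_widths),
                 dropout_rate_first_layer = dropout_rate_first_layer),
            class = "discriminator_spec")
}

#' GAN training configuration
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param iterations Optimizer steps; each step is one discriminator
#'   update plus one generator update (default 500).
#' @param batch_size Minibatch size (default 10).
#' @param seed Integer seed.
#' @return Object of class `gan_config`.
#' @export
gan_config <- function(learning_rate = 0.001, iterations = 500L, batch_size = 10L,
                       seed = 1L) {
  stopifnot(learning_rate > 0, iterations >= 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate, iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size), optimizer = "adam",
                 seed = as.integer(seed)),
            class = "gan_config")
}

#' Build an (untrained) GAN model pair
#'
#' @param gen A [generator_spec].
#' @param disc A [discriminator_spec].
#' @param n_channels,window_len Shape of the real windows; the
#'   generator's final width must equal `window_len`.
#' @param seed Integer seed for weight initialization.
#' @return Object of class `eeg_gan`.
#' @export
build_gan <- function(gen = generator_spec(), disc = discriminator_spec(),
                      n_channels = gen$n_channels,
                      window_len = gen$layer_widths[4], seed = 1L) {
  stopifnot(inherits(gen, "generator_spec"), inherits(disc, "discriminator_spec"))
  if (gen$layer_widths[4] != window_len) {
    stop("generator final width ", gen$layer_widths[4],
         " does not match window length ", window_len)
  }
  if (gen$n_channels != n_channels) stop("generator channel count mismatch")
  k <- gen$kernel_size
  f <- gen$n_filters
  L <- gen$layer_widths
  n_in <- n_channels * window_len
  dw <- disc$layer_widths
  local_seed(seed, {
    g <- list(
      W0 = glorot(gen$latent_dim, f[1] * L[1], c(gen$latent_dim, f[1] * L[1])),
      b0 = numeric(f[1] * L[1]),
      W1 = glorot(f[1] * k, f[2], c(f[2], f[1] * k)), b1 = numeric(f[2]),
      W2 = glorot(f[2] * k, f[3], c(f[3], f[2] * k)), b2 = numeric(f[3]),
      W3 = glorot(f[3] * k, n_channels, c(n_channels, f[3] * k)),
      b3 = numeric(n_channels))
    d <- list(
      W1 = glorot(n_in, dw[1], c(n_in, dw[1])), b1 = numeric(dw[1]),
      W2 = glorot(dw[1], dw[2], c(dw[1], dw[2])), b2 = numeric(dw[2]),
      W3 = glorot(dw[2], dw[3], c(dw[2], dw[3])), b3 = numeric(dw[3]),
      W4 = glorot(dw[3], dw[4], c(dw[3], dw[4])), b4 = numeric(dw[4]))
    structure(list(gen_spec = gen, disc_spec = disc, g = g, d = d,
                   n_channels = n_channels, window_len = window_len,
                   upsample = list(U1 = upsample_matrix(L[1], L[2]),
                                   U2 = upsample_matrix(L[2], L[3]),
                                   U3 = upsample_matrix(L[3], L[4])),
                   history = NULL, trained = FALSE),
              class = "eeg_gan")
  })
}

#' @export
print.eeg_gan <- function(x, ...) {
  cat("<eeg_gan> generator ", x$gen_spec$latent_dim, " -> [",
      paste(x$gen_spec$layer_widths, collapse = ", "), "] x ", x$n_channels,
      " channels; discriminator [", paste(x$disc_spec$layer_widths, collapse = ", "),
      "]; ", if (isTRUE(x$trained)) paste0("trained (", nrow(x$history), " iterations)")
      else "untrained", "\n", sep = "")
  invisible(x)
}

# Generator forward for a latent batch Z (B x latent). Returns the output
# array (C x L x B) and, when training, per-sample caches for backprop.
gen_forward <- function(model, Z, training = FALSE) {
  sp <- model$gen_spec; g <- model$g
  f <- sp$n_filters; L <- sp$layer_widths; k <- sp$kernel_size
  C <- model$n_channels
  B <- nrow(Z)
  tU1 <- t(model$upsample$U1); tU2 <- t(model$upsample$U2); tU3 <- t(model$upsample$U3)
  a0 <- dense_fwd(Z, g$W0, g$b0)
  r0 <- pmax(a0, 0)
  out <- array(0, c(C, L[4], B))
  caches <- if (training) vector("list", B) else NULL
  for (i in seq_len(B)) {
    x1 <- matrix(r0[i, ], f[1], L[1])
    u1 <- x1 %*% tU1
    c1 <- conv1d_fwd(u1, g$W1, g$b1, k); r1 <- pmax(c1$y, 0)
    u2 <- r1 %*% tU2
    c2 <- conv1d_fwd(u2, g$W2, g$b2, k); r2 <- pmax(c2$y, 0)
    u3 <- r2 %*% tU3
    c3 <- conv1d_fwd(u3, g$W3, g$b3, k)
    y <- sigmoid(c3$y)
    out[, , i] <- y
    if (training) caches[[i]] <- list(c1 = c1, c2 = c2, c3 = c3, a1 = c1$y,
                                      a2 = c2$y, y = y)
  }
  list(out = out, a0 = a0, caches = caches)
}

# Backprop through the generator. dOut: C x L4 x B gradient at the
# sigmoid output. Returns gradient list matching model$g.
gen_backward <- function(model, Z, fwd, dOut) {
  sp <- model$gen_spec; g <- model$g
  f <- sp$n_filters; L <- sp$layer_widths; k <- sp$kernel_size
  C <- model$n_channels
  B <- nrow(Z)
  U1 <- model$upsample$U1; U2 <- model$upsample$U2; U3 <- model$upsample$U3
  grads <- lapply(g, function(p) p * 0)
  dr0 <- matrix(0, B, f[1] * L[1])
  for (i in seq_len(B)) {
    cc <- fwd$caches[[i]]
    da3 <- dOut[, , i] * cc$y * (1 - cc$y)
    b3 <- conv1d_bwd(cc$c3, g$W3, da3, f[3], L[4], k)
    grads$W3 <- grads$W3 + b3$dW; grads$b3 <- grads$b3 + b3$db
    dr2 <- b3$dx %*% U3
    da2 <- dr2 * (cc$a2 > 0)
    b2 <- conv1d_bwd(cc$c2, g$W2, da2, f[2], L[3], k)
    grads$W2 <- grads$W2 + b2$dW; grads$b2 <- grads$b2 + b2$db
    dr1 <- b2$dx %*% U2
    da1 <- dr1 * (cc$a1 > 0)
    b1 <- conv1d_bwd(cc$c1, g$W1, da1, f[1], L[2], k)
    grads$W1 <- grads$W1 + b1$dW; grads$b1 <- grads$b1 + b1$db
    dr0[i, ] <- as.vector(b1$dx %*% U1)
  }
  da0 <- dr0 * (fwd$a0 > 0)
  grads$W0 <- t(Z) %*% da0
  grads$b0 <- colSums(da0)
  grads
}

# Discriminator forward on a flattened batch X (B x C*L). training
# enables first-layer dropout (inverted scaling).
disc_forward <- function(model, X, training = FALSE) {
  d <- model$d
  p <- model$disc_spec$dropout_rate_first_layer
  a1 <- dense_fwd(X, d$W1, d$b1); h1 <- lrelu(a1, 0.2)
  mask <- NULL
  if (training && p > 0) {
    mask <- matrix(stats::rbinom(length(h1), 1, 1 - p), nrow(h1)) / (1 - p)
    h1 <- h1 * mask
  }
  a2 <- dense_fwd(h1, d$W2, d$b2); h2 <- lrelu(a2, 0.2)
  a3 <- dense_fwd(h2, d$W3, d$b3); h3 <- lrelu(a3, 0.2)
  logits <- dense_fwd(h3, d$W4, d$b4)
  list(logits = logits, X = X, a1 = a1, h1 = h1, mask = mask,
       a2 = a2, h2 = h2, a3 = a3, h3 = h3)
}

# Backprop; dlogits: B x 1. Returns grads for model$d plus dX.
disc_backward <- function(model, fwd, dlogits) {
  d <- model$d
  g4 <- dense_bwd(fwd$h3, d$W4, dlogits)
  d3 <- g4$dX * lrelu_grad(fwd$a3, 0.2)
  g3 <- dense_bwd(fwd$h2, d$W3, d3)
  d2 <- g3$dX * lrelu_grad(fwd$a2, 0.2)
  g2 <- dense_bwd(fwd$h1, d$W2, d2)
  d1 <- g2$dX
  if (!is.null(fwd$mask)) d1 <- d1 * fwd$mask
  d1 <- d1 * lrelu_grad(fwd$a1, 0.2)
  g1 <- dense_bwd(fwd$X, d$W1, d1)
  list(grads = list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
                    W3 = g3$dW, b3 = g3$db, W4 = g4$dW, b4 = g4$db),
       dX = g1$dX)
}

#' Discriminator score for windows
#'
#' @param gan An [build_gan()] model.
#' @param windows `channels x samples` matrix or `channels x samples x n`
#'   array.
#' @return Numeric vector of real/fake probabilities in (0, 1).
#' @export
discriminate <- function(gan, windows) {
  stopifnot(inherits(gan, "eeg_gan"))
  if (is.matrix(windows)) windows <- array(windows, c(dim(windows), 1))
  B <- dim(windows)[3]
  X <- t(matrix(windows, dim(windows)[1] * dim(windows)[2], B))
  drop(sigmoid(disc_forward(gan, X)$logits))
}

#' Train a GAN on one class's windows
#'
#' Alternating non-saturating GAN training: each iteration performs one
#' Adam step on the discriminator (real vs generated batch, binary
#' cross-entropy) and one on the generator (maximizing the
#' discriminator's belief that generated windows are real). Deterministic
#' given the config seed on a fixed platform.
#'
#' @param real A [windowed_dataset] holding one class's (normalized)
#'   windows, or a `channels x samples x n` array; needs at least
#'   `batch_size` windows.
#' @param gen,disc Network specs; defaults sized by the real windows.
#' @param config A [gan_config].
#' @return A trained `eeg_gan` with a `history` data.frame
#'   (`iteration`, `d_loss`, `g_loss`).
#' @export
train_gan <- function(real, gen = NULL, disc = discriminator_spec(),
                      config = gan_config()) {
  if (inherits(real, "windowed_dataset")) real <- real$data
  stopifnot(is.array(real), length(dim(real)) == 3)
  C <- dim(real)[1]; L <- dim(real)[2]; n <- dim(real)[3]
  if (n < config$batch_size) {
    stop("need at least batch_size = ", config$batch_size, " real windows, got ", n)
  }
  if (is.null(gen)) {
    w <- as.integer(pmax(8, round(L * c(128, 256, 512) / 1250)))
    gen <- generator_spec(layer_widths = c(w, L), n_channels = C)
  }
  local_seed(config$seed, {
    model <- build_gan(gen, disc, n_channels = C, window_len = L,
                       seed = stats::runif(1, 1, 2^30))
    Xreal_all <- t(matrix(real, C * L, n))
    opt_d <- adam_state(model$d, lr = config$learning_rate, beta1 = 0.5)
    opt_g <- adam_state(model$g, lr = config$learning_rate, beta1 = 0.5)
    hist <- data.frame(iteration = seq_len(config$iterations),
                       d_loss = NA_real_, g_loss = NA_real_)
    B <- config$batch_size
    for (it in seq_len(config$iterations)) {
      idx <- sample.int(n, B, replace = n < B)
      Xr <- Xreal_all[idx, , drop = FALSE]
      Z <- matrix(stats::rnorm(B * gen$latent_dim), B)
      fake <- gen_forward(model, Z, training = TRUE)
      Xf <- t(matrix(fake$out, C * L, B))
      # --- discriminator step ---
      fr <- disc_forward(model, Xr, training = TRUE)
      lr_ <- bce_logits(fr$logits, matrix(1, B, 1))
      gr <- disc_backward(model, fr, lr_$dlogits)
      ff <- disc_forward(model, Xf, training = TRUE)
      lf <- bce_logits(ff$logits, matrix(0, B, 1))
      gf <- disc_backward(model, ff, lf$dlogits)
      dgrads <- Map(`+`, gr$grads, gf$grads)
      st <- adam_step(model$d, dgrads, opt_d)
      model$d <- st$params; opt_d <- st$state
      # --- generator step (non-saturating) ---
      fg <- disc_forward(model, Xf, training = TRUE)
      lg <- bce_logits(fg$logits, matrix(1, B, 1))
      bg <- disc_backward(model, fg, lg$dlogits)
      dOut <- array(t(bg$dX), c(C, L, B))
      ggrads <- gen_backward(model, Z, fake, dOut)
      st <- adam_step(model$g, ggrads, opt_g)
      model$g <- st$params; opt_g <- st$state
      hist$d_loss[it] <- lr_$loss + lf$loss
      hist$g_loss[it] <- lg$loss
      if (!is.finite(hist$d_loss[it]) || !is.finite(hist$g_loss[it])) {
        stop("non-finite GAN loss at iteration ", it)
      }
    }
    model$history <- hist
    model$trained <- TRUE
    model$config <- config
    model
  })
}

#' Sample windows from a trained generator
#'
#' @param gan An `eeg_gan`.
#' @param n Number of windows (`>= 0`).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return `channels x samples x n` array.
#' @export
synthesize_windows <- function(gan, n, seed = NULL) {
  stopifnot(inherits(gan, "eeg_gan"), n >= 0)
  if (n == 0) return(array(0, c(gan$n_channels, gan$window_len, 0)))
  local_seed(seed, {
    Z <- matrix(stats::rnorm(n * gan$gen_spec$latent_dim), n)
    gen_forward(gan, Z, training = FALSE)$out
  })
}

#' Augment one class to a target window count
#'
#' Trains a GAN on the class's windows and appends synthetic windows
#' until the class holds `target_count` windows. Real windows are never
#' mutated or dropped; synthetic windows are flagged in the provenance
#' table.
#'
#' @param class_windows A [windowed_dataset] holding a single class
#'   (typically the training split, already normalized to `[0, 1]`).
#' @param target_count Total windows after augmentation (default 2920).
#' @param gen,disc,config Passed to [train_gan()].
#' @return A [windowed_dataset] of `target_count` windows; the attribute
#'   `"gan"` carries the trained model.
#' @export
augment_to_count <- function(class_windows, target_count = 2920L,
                             gen = NULL, disc = discriminator_spec(),
                             config = gan_config()) {
  stopifnot(inherits(class_windows, "windowed_dataset"))
  lab <- unique(class_windows$labels)
  if (length(lab) != 1) stop("augment_to_count expects a single-class dataset")
  n_real <- n_windows(class_windows)
  if (target_count < n_real) {
    stop("target_count ", target_count, " is below the current count ", n_real)
  }
  if (target_count == n_real) return(class_windows)
  gan <- train_gan(class_windows, gen = gen, disc = disc, config = config)
  n_syn <- target_count - n_real
  syn <- synthesize_windows(gan, n_syn, seed = derive_seed(config$seed, 13L))
  syn_ds <- windowed_dataset(
    syn, rep(lab, n_syn), class_windows$fs, class_windows$channel_labels,
    provenance = data.frame(
      window_id = max(class_windows$provenance$window_id) + seq_len(n_syn),
      class_id = lab, seed = derive_seed(config$seed, 13L), synthetic = TRUE))
  out <- bind_windows(class_windows, syn_ds)
  attr(out, "gan") <- gan
  out
}
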