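replica_arch <- function() architecture_spec()  # 2920-width replica, 4 classes

test_that("parameter accounting reproduces the width-replica table", {
  tab <- count_parameters(replica_arch())
  expect_equal(tab$weights_per_order[1:5],
               c(8526400, 4263200, 1065800, 266450, 65700))
  expect_equal(tab$bias[1:5], c(2920, 1460, 730, 365, 180))
  expect_equal(attr(tab, "flatten_dim"), 720)
  expect_equal(tab$weights[tab$layer == "fc"], 2880)
  # degenerate: no layers, no head
  empty <- architecture_spec(feature_chain = 5L, cheb_orders = integer(0),
                             n_classes = 0L)
  etab <- count_parameters(empty)
  expect_equal(nrow(etab), 0)
  expect_equal(attr(etab, "grand_total"), 0)
})

test_that("parameter accounting equals brute-force enumeration of arrays", {
  set.seed(11)
  g <- channel_graph(random_symmetric_adjacency(4, seed = 5), threshold = 0)
  for (i in 1:40) {
    n_layers <- sample(1:4, 1)
    chain <- sample(2:12, n_layers + 1, replace = TRUE)
    orders <- sample(1:4, n_layers, replace = TRUE)
    spec <- architecture_spec(feature_chain = chain, cheb_orders = orders,
                              n_nodes = 4, n_classes = sample(2:5, 1))
    tab <- count_parameters(spec)
    model <- build_gcn(spec, g, seed = i, init = "glorot")
    enumerated <- sum(vapply(model$params, length, 0L))
    expect_equal(attr(tab, "grand_total"), enumerated)
    # per-layer weight tensors have exactly C_k * in * out elements
    for (l in seq_len(n_layers)) {
      expect_equal(length(model$params[[paste0("W", l)]]),
                   orders[l] * chain[l] * chain[l + 1])
    }
  }
})

test_that("forward pass produces softmax probabilities of the right shape", {
  g <- channel_graph(random_symmetric_adjacency(4, seed = 6), threshold = 0)
  spec <- architecture_spec(feature_chain = c(10, 8, 6), cheb_orders = c(2, 2),
                            n_nodes = 4, n_classes = 3)
  m <- build_gcn(spec, g, seed = 2)
  m$classes <- 0:2
  m$trained <- TRUE
  X <- array(rnorm(4 * 10 * 5), c(4, 10, 5))
  p <- predict(m, X, type = "prob")
  expect_equal(dim(p), c(5, 3))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  expect_error(build_gcn(spec, channel_graph(random_symmetric_adjacency(3), threshold = 0)),
               "nodes")
  expect_error(predict(m, array(0, c(4, 7, 2))), "width")
})

test_that("edgeless graph collapses ChebConv to a dense layer with summed weights", {
  suppressWarnings(g <- channel_graph(matrix(0, 4, 4), threshold = 0))
  spec <- architecture_spec(feature_chain = c(6, 5), cheb_orders = 3L,
                            n_nodes = 4, n_classes = 2, dropout_rate = 0)
  m <- build_gcn(spec, g, seed = 3, init = "glorot")
  X <- array(rnorm(4 * 6 * 7), c(4, 6, 7))
  fwd <- gcn_forward(m, X, training = FALSE)
  # oracle: per-node dense layer with weight sum_k W_k (T_k(I) = I)
  Wsum <- apply(m$params$W1, c(1, 2), sum)
  ls <- spec$layers[[1]]
  dense <- array(0, c(4, 5, 7))
  for (b in 1:7) {
    dense[, , b] <- sweep(X[, , b] %*% Wsum, 2, m$params$b1, `+`)
  }
  act <- lrelu(matrix(aperm(dense, c(1, 3, 2)), 4 * 7, 5), ls$leaky_slope)
  bn <- sweep(sweep(act, 2, m$bn_state[[1]]$mean), 2,
              sqrt(m$bn_state[[1]]$var + 1e-5), `/`)
  flat_oracle <- matrix(aperm(array(bn, c(4, 7, 5)), c(1, 3, 2)), 20, 7)
  logits_oracle <- sweep(t(flat_oracle) %*% m$params$Wfc, 2, m$params$bfc, `+`)
  expect_lt(max(abs(fwd$logits - logits_oracle)), 1e-8)
})

test_that("order-1 layers are graph independent", {
  spec <- architecture_spec(feature_chain = c(8, 6, 4), cheb_orders = c(1, 1),
                            n_nodes = 4, n_classes = 2, dropout_rate = 0)
  gA <- channel_graph(random_symmetric_adjacency(4, seed = 8), threshold = 0)
  gB <- channel_graph(random_symmetric_adjacency(4, seed = 9), threshold = 0)
  mA <- build_gcn(spec, gA, seed = 4)
  mB <- build_gcn(spec, gB, seed = 4)
  X <- array(rnorm(4 * 8 * 3), c(4, 8, 3))
  expect_equal(gcn_forward(mA, X)$logits, gcn_forward(mB, X)$logits,
               tolerance = 1e-12)
})

test_that("stratified split honors floor-then-remainder counts and is order-insensitive", {
  ds <- small_cohort(n = 10, seed = 14)
  sp <- split_dataset(ds, seed = 3)
  expect_equal(vapply(sp, n_windows, 0L),
               c(train = 14L, val = 4L, test = 2L))
  for (s in sp) expect_equal(unname(table(s$labels)), rep(n_windows(s) / 2, 2),
                             ignore_attr = TRUE)
  # disjoint and exhaustive
  ids <- sort(unname(unlist(lapply(sp, function(s) s$provenance$window_id))))
  expect_equal(ids, sort(ds$provenance$window_id))
  # shuffled input, same seed -> identical partition (as window-id sets)
  perm <- sample(n_windows(ds))
  sp2 <- split_dataset(subset_windows(ds, perm), seed = 3)
  for (nm in names(sp)) {
    expect_setequal(sp2[[nm]]$provenance$window_id, sp[[nm]]$provenance$window_id)
  }
  # the printed per-class arithmetic for the full-scale count
  big <- windowed_dataset(array(rnorm(2 * 2 * 2920), c(2, 2, 2920)),
                          rep(0L, 2920), fs = 250)
  spb <- split_dataset(big, seed = 9)
  expect_equal(unname(vapply(spb, n_windows, 0L)), c(2044L, 584L, 292L))
  expect_error(split_dataset(subset_windows(ds, c(1, 2, 11)), seed = 1),
               "fewer than 3")
})

test_that("training bookkeeping: epoch count, history, errors", {
  ds <- small_cohort(n = 12, seed = 15)
  sp <- lapply(split_dataset(ds, seed = 1), preprocess_windows)
  arch <- architecture_spec(feature_chain = c(64, 8, 4), cheb_orders = c(1, 1),
                            n_nodes = 4, n_classes = 2)
  g <- channel_graph(sp$train, threshold = 0.2)
  m <- build_gcn(arch, g, seed = 1)
  tr <- train_gcn(m, sp$train, sp$val, gcn_control(epochs = 1, seed = 2))
  expect_equal(nrow(tr$history), 1)
  expect_true(all(is.finite(unlist(tr$history[-1]))))
  expect_length(tr$val_accuracy, 1)
  # all-one-class labels vs a 2-class architecture
  one <- subset_windows(sp$train, which(sp$train$labels == 0))
  expect_error(train_gcn(build_gcn(arch, g, seed = 1), one, one, gcn_control(epochs = 1)),
               "classes")
})

test_that("inference is deterministic and batches map to one label each", {
  ds <- small_cohort(n = 12, seed = 16)
  sp <- lapply(split_dataset(ds, seed = 1), preprocess_windows)
  arch <- architecture_spec(feature_chain = c(64, 8, 4), cheb_orders = c(1, 1),
                            n_nodes = 4, n_classes = 2)
  m <- fatigue_gcn(sp$train, sp$val, arch = arch,
                   control = gcn_control(epochs = 2, seed = 3),
                   graph_threshold = 0.2)
  p1 <- predict(m, sp$train, type = "prob")
  p2 <- predict(m, sp$train, type = "prob")
  expect_identical(p1, p2)
  labs <- predict(m, sp$test)
  expect_length(labs, n_windows(sp$test))
  expect_true(all(labs %in% c(0L, 4L)))
})

test_that("the model can overfit a tiny training set (capacity check)", {
  ds <- small_cohort(n = 8, seed = 17)          # 16 windows
  dsn <- preprocess_windows(ds)
  arch <- smoke_architecture(n_classes = 2)
  g <- channel_graph(dsn, threshold = 0.2)
  m <- build_gcn(arch, g, seed = 5)
  tr <- train_gcn(m, dsn, dsn, gcn_control(epochs = 200, learning_rate = 1e-2,
                                           weight_decay = 0, batch_size = 16,
                                           seed = 6))
  expect_lt(min(tr$history$train_loss), 0.05)
})

test_that("model methods print, summarize and plot without error", {
  ds <- small_cohort(n = 12, seed = 18)
  sp <- lapply(split_dataset(ds, seed = 1), preprocess_windows)
  arch <- architecture_spec(feature_chain = c(64, 8, 4), cheb_orders = c(1, 1),
                            n_nodes = 4, n_classes = 2)
  m <- fatigue_gcn(sp$train, sp$val, arch = arch,
                   control = gcn_control(epochs = 2, seed = 3),
                   graph_threshold = 0.2)
  expect_output(print(m), "fatigue_gcn")
  expect_output(summary(m), "Parameter accounting")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(m))
})
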