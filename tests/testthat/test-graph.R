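test_that("correlation adjacency matches the textbook formula and conventions", {
  set.seed(1)
  x <- matrix(rnorm(4 * 200), 4, 200)
  ds <- windowed_dataset(array(x, c(4, 200, 1)), 0L, fs = 250)
  A <- correlation_adjacency(ds)
  # direct covariance / std-product oracle
  oracle <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    if (i != j) {
      oracle[i, j] <- abs(mean((x[i, ] - mean(x[i, ])) * (x[j, ] - mean(x[j, ]))) /
                            (sd(x[i, ]) * sd(x[j, ]) * (199 / 200)))
    }
  }
  expect_lt(max(abs(A - oracle)), 1e-12)
  expect_equal(diag(A), rep(0, 4), ignore_attr = TRUE)
  # identical and negated channels give |r| = 1
  y <- rbind(x[1, ], x[1, ], -x[1, ])
  dsy <- windowed_dataset(array(y, c(3, 200, 1)), 0L, fs = 250)
  Ay <- correlation_adjacency(dsy)
  expect_equal(Ay[1, 2], 1)
  expect_equal(Ay[1, 3], 1)
  const <- rbind(x[1, ], rep(2, 200))
  dsc <- windowed_dataset(array(const, c(2, 200, 1)), 0L, fs = 250,
                          channel_labels = c("P4", "C3"))
  expect_error(correlation_adjacency(dsc), "C3")
})

test_that("sparsify thresholds correctly and preserves weights and symmetry", {
  A <- random_symmetric_adjacency(6, seed = 2)
  expect_equal(sparsify(A, 0), A)
  s <- sparsify(A, 0.5)
  expect_equal(sum(s[upper.tri(s)] != 0),
               sum(A[upper.tri(A)] >= 0.5))      # exhaustive-scan oracle
  expect_true(all(s[s != 0] == A[s != 0]))
  expect_equal(s, t(s))
  b <- sparsify(A, 0.5, binarize = TRUE)
  expect_true(all(b %in% c(0, 1)))
  A1 <- A; A1[1, 2] <- A1[2, 1] <- 1
  expect_equal(sum(sparsify(A1, 1) != 0), 2)
  expect_error(sparsify(A, 1.5), "threshold")
  expect_error(sparsify(A, -0.1), "threshold")
})

test_that("normalized Laplacian has the expected closed forms and spectrum", {
  expect_equal(normalized_laplacian(matrix(0, 4, 4)), diag(4))
  A2 <- matrix(c(0, 1, 1, 0), 2)
  L2 <- normalized_laplacian(A2)
  expect_equal(L2, matrix(c(1, -1, -1, 1), 2))
  expect_equal(sort(eigen(L2, only.values = TRUE)$values), c(0, 2))
  for (s in 1:10) {
    A <- random_symmetric_adjacency(6, seed = s)
    ev <- eigen(normalized_laplacian(A), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
    expect_lt(max(ev), 2 + 1e-8)
    expect_lt(abs(min(ev)), 1e-8)
  }
  expect_error(normalized_laplacian(matrix(c(0, -1, -1, 0), 2)), "non-negative")
})

test_that("scaled Laplacian maps the spectrum into [-1, 1]", {
  sc <- scaled_laplacian(diag(4))
  expect_equal(sc$L_scaled, diag(4))
  expect_equal(sc$lambda_max, 1)
  L2 <- matrix(c(1, -1, -1, 1), 2)
  sc2 <- scaled_laplacian(L2)
  expect_equal(sc2$lambda_max, 2)
  expect_equal(sc2$L_scaled, matrix(c(0, -1, -1, 0), 2))
  expect_equal(sort(eigen(sc2$L_scaled, only.values = TRUE)$values), c(-1, 1))
  for (s in 1:10) {
    A <- random_symmetric_adjacency(5, seed = 100 + s)
    sc <- scaled_laplacian(normalized_laplacian(A))
    ev <- eigen(sc$L_scaled, symmetric = TRUE, only.values = TRUE)$values
    expect_lt(max(abs(ev)), 1 + 1e-8)
  }
  expect_error(scaled_laplacian(matrix(0, 3, 3)), "lambda_max")
})

test_that("chebyshev basis satisfies the recursion's closed forms", {
  A <- random_symmetric_adjacency(4, seed = 3)
  sc <- scaled_laplacian(normalized_laplacian(A))
  Lt <- sc$L_scaled
  set.seed(4)
  X <- matrix(rnorm(4 * 3), 4, 3)
  expect_equal(chebyshev_basis(Lt, X, 1), list(X))
  # T_k(1) = 1: identity L gives back X at every order
  b_id <- chebyshev_basis(diag(4), X, 2)
  expect_equal(b_id[[2]], X)
  b <- chebyshev_basis(Lt, X, 4)
  # explicit matrix-power closed form for T_3
  expect_lt(max(abs(b[[4]] - (4 * Lt %*% Lt %*% Lt - 3 * Lt) %*% X)), 1e-9)
  # spectral route: U T_3(Lambda) U' X
  e <- eigen(Lt, symmetric = TRUE)
  lam <- pmin(pmax(e$values, -1), 1)
  T3 <- e$vectors %*% diag(cos(3 * acos(lam))) %*% t(e$vectors) %*% X
  expect_lt(max(abs(b[[4]] - T3)), 1e-9)
  expect_error(chebyshev_basis(Lt, X, 0), "K")
})

test_that("recursion matches the eigendecomposition oracle on random graphs", {
  for (s in 1:25) {
    n <- sample(2:8, 1)
    A <- random_symmetric_adjacency(n, seed = 1000 + s)
    sc <- scaled_laplacian(normalized_laplacian(A))
    X <- matrix(rnorm(n * 2), n, 2)
    K <- sample(1:6, 1)
    b <- chebyshev_basis(sc$L_scaled, X, K)
    e <- eigen(sc$L_scaled, symmetric = TRUE)
    lam <- pmin(pmax(e$values, -1), 1)
    for (k in seq_len(K)) {
      Tk <- e$vectors %*% diag(cos((k - 1) * acos(lam)), n) %*% t(e$vectors)
      expect_lt(max(abs(b[[k]] - Tk %*% X)), 1e-8)
    }
  }
})

test_that("chebyshev basis is permutation equivariant", {
  n <- 5
  A <- random_symmetric_adjacency(n, seed = 77)
  sc <- scaled_laplacian(normalized_laplacian(A))
  set.seed(78)
  X <- matrix(rnorm(n * 3), n, 3)
  perm <- sample(n)
  P <- diag(n)[perm, ]
  b <- chebyshev_basis(sc$L_scaled, X, 4)
  bp <- chebyshev_basis(P %*% sc$L_scaled %*% t(P), P %*% X, 4)
  for (k in 1:4) expect_lt(max(abs(bp[[k]] - P %*% b[[k]])), 1e-10)
})

test_that("channel_graph assembles consistent spectral machinery", {
  ds <- small_cohort(n = 20, seed = 31)
  expect_warning(g0 <- channel_graph(ds, threshold = 0.99), "disconnected")
  g <- channel_graph(ds, threshold = 0.2)
  expect_s3_class(g, "channel_graph")
  expect_equal(g$adjacency, t(g$adjacency))
  expect_equal(diag(g$degree), rowSums(g$adjacency), ignore_attr = TRUE)
  ev <- eigen(g$laplacian_scaled, only.values = TRUE)$values
  expect_lt(max(abs(ev)), 1 + 1e-8)
  # threshold-0 sparsify path equals the dense path exactly
  gd <- channel_graph(ds, threshold = 0)
  expect_equal(gd$adjacency, correlation_adjacency(ds))
  expect_equal(gd$laplacian_norm,
               normalized_laplacian(correlation_adjacency(ds)))
})

test_that("graph edge-list round trip preserves the graph", {
  ds <- small_cohort(n = 15, seed = 33)
  g <- channel_graph(ds, threshold = 0.2)
  dir <- withr::local_tempdir()
  write_graph(g, dir)
  g2 <- read_graph(dir)
  expect_equal(unname(g2$adjacency), unname(g$adjacency), tolerance = 1e-12)
  expect_equal(g2$lambda_max, g$lambda_max, tolerance = 1e-10)
})
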