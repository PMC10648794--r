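test_that("PCA recovers the hand-computed eigenstructure of collinear points", {
  x <- matrix(c(-2, -2, -1, -1, 1, 1, 2, 2), ncol = 2, byrow = TRUE)
  m <- fit_pca(x, 2)
  expect_equal(m$components[1, ], c(1, 1) / sqrt(2), tolerance = 1e-10)
  expect_equal(m$explained_variance[2], 0, tolerance = 1e-10)
  # transforming the training mean gives the origin
  expect_equal(as.vector(pca_transform(m, m$mean)), c(0, 0), tolerance = 1e-12)
})

test_that("PCA components are orthonormal, variance-ordered and sign-fixed", {
  set.seed(5)
  x <- matrix(rnorm(200 * 12), 200, 12) %*% matrix(rnorm(144), 12, 12)
  m <- fit_pca(x, 8)
  expect_equal(m$components %*% t(m$components), diag(8), tolerance = 1e-6)
  expect_true(all(diff(m$explained_variance) <= 1e-9))
  for (i in 1:8) {
    expect_gt(m$components[i, which.max(abs(m$components[i, ]))], 0)
  }
  # full-rank reconstruction is exact
  mf <- fit_pca(x, 12)
  z <- pca_transform(mf, x)
  xr <- sweep(z %*% mf$components, 2, mf$mean, "+")
  expect_equal(xr, x, tolerance = 1e-8)
  # zero-variance feature gets zero loadings on variance-carrying components
  x0 <- cbind(x, 3)
  m0 <- fit_pca(x0, 8)
  expect_equal(m0$components[, 13], rep(0, 8), tolerance = 1e-8)
})

test_that("orthogonal projection contracts pairwise distances", {
  set.seed(6)
  x <- matrix(rnorm(40 * 10), 40, 10)
  m <- fit_pca(x, 4)
  z <- pca_transform(m, x)
  df <- as.matrix(dist(x))
  dz <- as.matrix(dist(z))
  expect_true(all(dz <= df + 1e-9))
})

test_that("PCA rejects invalid dimensions", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(fit_pca(x, 3), "n_components")
  expect_error(fit_pca(x[1, , drop = FALSE], 1), "2 samples")
  m <- fit_pca(x, 2)
  expect_error(pca_transform(m, matrix(0, 2, 5)), "width")
})

test_that("ReliefF reproduces the hand-computed toy weights", {
  x <- matrix(c(0, 0, 1, 1), ncol = 1)
  y <- c(0, 0, 1, 1)
  w <- relieff_weights(x, y, relieff_config(k_neighbors = 1))
  # every hit-diff 0, every miss-diff 1 over 4 iterations: weight exactly 1
  expect_identical(w$weights, 1)
  # a constant feature keeps weight exactly 0
  x2 <- cbind(x, 5)
  w2 <- relieff_weights(x2, y, relieff_config(k_neighbors = 1))
  expect_identical(w2$weights[2], 0)
})

test_that("streamlined ReliefF matches the naive reference exactly", {
  set.seed(13)
  for (rep in 1:12) {
    n <- sample(10:50, 1)
    d <- sample(2:20, 1)
    x <- matrix(rnorm(n * d), n, d)
    y <- rep_len(c(0, 1), n)
    k <- sample(seq_len(min(table(y)) - 1), 1)
    w <- relieff_weights(x, y, relieff_config(k_neighbors = k))
    expect_equal(w$weights, naive_relieff(x, y, k), tolerance = 1e-10)
  }
})

test_that("ReliefF ranks a separating feature first and noise near zero", {
  for (s in 1:20) {
    set.seed(s)
    n <- 100
    sep <- c(rnorm(n / 2, 0, 0.05), rnorm(n / 2, 1, 0.05))
    x <- cbind(sep, matrix(runif(n * 9), n, 9))
    y <- rep(c(0, 1), each = n / 2)
    w <- relieff_weights(x, y, relieff_config(k_neighbors = 5))
    expect_identical(which.max(w$weights), 1L)
    expect_true(all(abs(w$weights[-1]) <= 0.15))
  }
})

test_that("ReliefF is permutation-equivariant and label-symmetric", {
  set.seed(3)
  x <- matrix(rnorm(30 * 6), 30, 6)
  y <- rep_len(c(0, 1), 30)
  w <- relieff_weights(x, y, relieff_config(k_neighbors = 3))
  perm <- c(4, 1, 6, 2, 5, 3)
  wp <- relieff_weights(x[, perm], y, relieff_config(k_neighbors = 3))
  expect_equal(wp$weights, w$weights[perm], tolerance = 1e-12)
  wf <- relieff_weights(x, 1 - y, relieff_config(k_neighbors = 3))
  expect_equal(wf$weights, w$weights, tolerance = 1e-12)
  # sequential default pass is bit-reproducible
  expect_identical(
    relieff_weights(x, y, relieff_config(k_neighbors = 3))$weights,
    w$weights
  )
})

test_that("ReliefF rejects degenerate inputs", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(relieff_weights(x, rep(1, 5)), "both classes")
  expect_error(
    relieff_weights(x, c(0, 0, 1, 1, 1), relieff_config(k_neighbors = 2)),
    "smaller than the smallest class"
  )
})

test_that("top-k selection sorts by weight with index tie-breaks", {
  sel <- top_k_indices(c(0.2, 0.9, 0.5), 2)
  expect_identical(sel$indices, c(2L, 3L))
  expect_identical(top_k_indices(rep(0.5, 3), 3)$indices, 1:3)
  set.seed(8)
  for (rep in 1:10) {
    w <- rnorm(50)
    n <- sample(50, 1)
    sel <- top_k_indices(w, n)
    oracle <- order(-w, seq_along(w))[seq_len(n)]
    expect_identical(sel$indices, oracle)
  }
  expect_error(top_k_indices(c(1, 2), 3), "n_selected")
  td <- tidy(relieff_weights(matrix(c(0, 0, 1, 1), ncol = 1), c(0, 0, 1, 1),
    config = relieff_config(k_neighbors = 1)
  ))
  expect_identical(td$rank, 1L)
})
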