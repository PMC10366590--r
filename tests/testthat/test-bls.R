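test_that("feature and enhancement node maps follow their defining formulas", {
  set.seed(20)
  X <- matrix(rnorm(15), 5, 3)

  expect_equal(feature_nodes(X, diag(3), numeric(3), "identity"), X)

  b <- c(0.3, -0.2)
  D0 <- feature_nodes(matrix(0, 4, 3), matrix(0, 3, 2), b, "tanh")
  expect_equal(D0, matrix(tanh(b), 4, 2, byrow = TRUE))

  W <- matrix(rnorm(6), 3, 2); bb <- rnorm(2)
  D <- feature_nodes(X, W, bb, "identity")
  ref <- matrix(0, 5, 2)
  for (i in 1:5) for (j in 1:2) {
    acc <- bb[j]
    for (k in 1:3) acc <- acc + X[i, k] * W[k, j]
    ref[i, j] <- acc
  }
  expect_equal(D, ref, tolerance = 1e-10)
  expect_error(feature_nodes(X, matrix(0, 4, 2), numeric(2)), "mismatch")

  E0 <- enhancement_nodes(matrix(0, 3, 2), matrix(rnorm(8), 2, 4), numeric(4))
  expect_equal(E0, matrix(0, 3, 4))
  E <- enhancement_nodes(X, matrix(rnorm(9), 3, 3), rnorm(3), "tanh")
  expect_true(all(E > -1 & E < 1))
  expect_equal(enhancement_nodes(X, W, bb, "tanh"), tanh(ref), tolerance = 1e-10)
})

test_that("ridge pseudo-inverse matches closed forms and the dense oracle", {
  lam <- 0.5
  expect_equal(ridge_pinv(diag(4), lam), diag(4) / (1 + lam))

  # Moore-Penrose limit on orthonormal columns
  set.seed(21)
  Q <- qr.Q(qr(matrix(rnorm(20 * 5), 20, 5)))
  expect_equal(ridge_pinv(Q, 1e-12) %*% Q, diag(5), tolerance = 1e-6)

  G <- matrix(rnorm(50 * 30), 50, 30)
  expect_equal(ridge_pinv(G, 1e-8), ridge_pinv_oracle(G, 1e-8),
               tolerance = 1e-8)
  # dual (wide) branch agrees with the same dense formula
  Gw <- matrix(rnorm(20 * 60), 20, 60)
  expect_equal(ridge_pinv(Gw, 1e-6), ridge_pinv_oracle(Gw, 1e-6),
               tolerance = 1e-7)

  G[1, 1] <- NA
  expect_error(ridge_pinv(G, 1e-8), "non-finite")
  expect_error(ridge_pinv(Gw, 0), "lam")
})

test_that("output-weight solve minimizes the ridge objective", {
  set.seed(22)
  G <- matrix(rnorm(30 * 30), 30, 30)
  W <- fit_output_weights(G, G, 1e-10)
  expect_equal(W, diag(30), tolerance = 1e-5)

  G <- matrix(rnorm(40 * 20), 40, 20)
  Y <- matrix(rnorm(40 * 2), 40, 2)
  lam <- 0.1
  W <- fit_output_weights(G, Y, lam)
  expect_equal(W, fit_weights_oracle(G, Y, lam), tolerance = 1e-8)

  obj <- ridge_objective(G, Y, W, lam)
  for (i in 1:100) {
    pert <- W + matrix(rnorm(length(W), sd = 0.01), nrow(W))
    expect_gte(ridge_objective(G, Y, pert, lam), obj)
  }
})

test_that("||W|| is non-increasing along the ridge path", {
  set.seed(23)
  G <- matrix(rnorm(50 * 25), 50, 25)
  Y <- matrix(rnorm(50 * 3), 50, 3)
  norms <- vapply(c(1e-8, 1e-4, 1e-2, 1, 100, 1e4),
                  function(l) norm(fit_output_weights(G, Y, l), "F"),
                  numeric(1))
  expect_true(all(diff(norms) <= 1e-10))
})

test_that("appending enhancement nodes never worsens the training objective", {
  set.seed(24)
  lam <- 1e-3
  for (rep in 1:20) {
    n <- sample(20:60, 1)
    G <- matrix(rnorm(n * 10), n, 10)
    extra <- matrix(rnorm(n * 5), n, 5)
    Y <- matrix(rnorm(n * 2), n, 2)
    o_small <- ridge_objective(G, Y, fit_output_weights(G, Y, lam), lam)
    G2 <- cbind(G, extra)
    o_big <- ridge_objective(G2, Y, fit_output_weights(G2, Y, lam), lam)
    expect_lte(o_big, o_small + 1e-9)
  }
})

test_that("sparse auto-coding reduces to least squares and shrinks with sparsity", {
  set.seed(25)
  # full-column-rank case: direct match with the normal-equations oracle
  Xf <- matrix(rnorm(40 * 12), 40, 12)
  W0f <- matrix(runif(12 * 8, -1, 1), 12, 8)
  b0f <- runif(8, -1, 1)
  Zf <- sweep(Xf %*% W0f, 2, b0f, "+")
  expect_equal(sparse_autoencode_weights(Xf, W0f, b0f, sparsity = 0),
               solve(crossprod(Zf), crossprod(Zf, Xf)), tolerance = 1e-6)

  # rank-deficient case (more nodes than input dims, the BLS norm): the fit
  # must reach the least-squares optimum, checked against the ridge limit
  X <- matrix(rnorm(40 * 6), 40, 6)
  W0 <- matrix(runif(6 * 10, -1, 1), 6, 10)
  b0 <- runif(10, -1, 1)
  Z <- sweep(X %*% W0, 2, b0, "+")
  Wls <- sparse_autoencode_weights(X, W0, b0, sparsity = 0)
  expect_equal(Z %*% Wls, Z %*% fit_weights_oracle(Z, X, 1e-6),
               tolerance = 1e-5)

  Wsp <- suppressWarnings(sparse_autoencode_weights(X, W0, b0, sparsity = 0.5))
  Whuge <- sparse_autoencode_weights(X, W0, b0, sparsity = 1e6)
  expect_lt(norm(Whuge, "F"), norm(Wls, "F"))
  expect_lte(norm(Wsp, "F"), norm(Wls, "F") + 1e-8)

  expect_identical(Wsp, suppressWarnings(
    sparse_autoencode_weights(X, W0, b0, sparsity = 0.5)))
  expect_warning(sparse_autoencode_weights(X, W0, b0, sparsity = 0.5,
                                           max_iter = 2L, tol = 0),
                 "did not converge")
})

gaussian_2class <- function(n = 200, d = 20, sep = 3, seed = 0) {
  set.seed(seed)
  y <- rep(c("A", "B"), each = n / 2)
  X <- matrix(rnorm(n * d), n, d)
  X[, 1] <- X[, 1] + ifelse(y == "A", sep, -sep)
  list(X = X, y = y)
}

test_that("BLS fitting is deterministic and separates well-separated Gaussians", {
  gd <- gaussian_2class()
  cfg <- bls_config(n_feature_nodes = 100, n_enh_nodes = 20, mode = "classic",
                    lam = 1e-8, seed = 1)
  m1 <- bls_fit(gd$X, gd$y, config = cfg)
  m2 <- bls_fit(gd$X, gd$y, config = cfg)
  expect_identical(m1$W_out, m2$W_out)

  pred <- predict(m1, gd$X)
  expect_gte(mean(pred$labels == gd$y), 0.99)
  # probability view is a proper softmax of the scores
  expect_equal(rowSums(pred$prob), rep(1, nrow(gd$X)))
  expect_equal(max.col(pred$prob), max.col(pred$scores))
})

test_that("classic-mode fitting equals the manual original-BLS wiring", {
  gd <- gaussian_2class(n = 60, d = 8, seed = 5)
  cfg <- bls_config(n_feature_nodes = 24, n_enh_nodes = 12,
                    n_feature_groups = 3, n_enh_groups = 2,
                    mode = "classic", lam = 1e-3, seed = 9)
  m <- bls_fit(gd$X, gd$y, config = cfg)
  D <- feature_nodes(gd$X, m$W_e, m$b_e, cfg$phi)
  E <- enhancement_nodes(D, m$W_h, m$b_h, cfg$delta)
  G <- cbind(D, E)
  Y <- cbind(as.numeric(gd$y == "A"), as.numeric(gd$y == "B"))
  expect_equal(unname(m$W_out), unname(fit_weights_oracle(G, Y, cfg$lam)),
               tolerance = 1e-8)
  expect_equal(ncol(D), 24L)
  expect_equal(ncol(E), 12L)
})

test_that("ensemble mode wires enhancement nodes to the deep features", {
  gd <- gaussian_2class(n = 40, d = 6, seed = 6)
  Xe <- matrix(rnorm(40 * 10), 40, 10)
  cfg <- bls_config(n_feature_nodes = 12, n_enh_nodes = 8, lam = 1e-6, seed = 2)
  m <- bls_fit(gd$X, gd$y, Xe, cfg)
  expect_equal(nrow(m$W_h[[1]]), 10L)   # reads X_e, not D
  expect_error(bls_fit(gd$X, gd$y, config = cfg), "requires the deep")

  # prediction on a single sample equals the corresponding batched row
  pb <- predict(m, gd$X, Xe)
  p1 <- predict(m, gd$X[3, , drop = FALSE], Xe[3, , drop = FALSE])
  expect_equal(p1$scores[1, ], pb$scores[3, ])
  expect_equal(p1$labels, pb$labels[3])
})

test_that("prediction breaks score ties toward the first class", {
  gd <- gaussian_2class(n = 20, d = 4, seed = 7)
  m <- bls_fit(gd$X, gd$y, config = bls_config(n_feature_nodes = 8,
                                               n_enh_nodes = 4,
                                               mode = "classic", seed = 1))
  m$W_out[] <- 0
  pred <- predict(m, gd$X)
  expect_true(all(pred$labels == m$classes[1]))
})

test_that("sweep-mode validation enforces the hyperparameter ranges", {
  expect_error(bls_config(n_feature_nodes = 100, sweep_mode = TRUE),
               "outside sweep range")
  expect_error(bls_config(n_feature_nodes = 500, n_enh_nodes = 50,
                          sweep_mode = TRUE), "outside sweep range")
  expect_error(bls_config(n_feature_nodes = 500, n_enh_nodes = 100,
                          sparsity = 0.9, sweep_mode = TRUE),
               "outside sweep range")
  expect_s3_class(bls_config(n_feature_nodes = 500, n_enh_nodes = 100,
                             sparsity = 0.4, sweep_mode = TRUE), "bls_config")
  expect_error(bls_config(n_feature_nodes = 10, n_feature_groups = 3), "divide")
})
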