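# Random feature layer, Fourier features and kernel blocks.

test_that("feature layer has the contracted shape and determinism", {
  X <- matrix(rnorm(20), 5, 4)
  fl <- fit_feature_layer(X, n_groups = 2, nodes_per_group = 3, seed = 1)
  expect_equal(dim(fl$Z), c(5, 6))
  expect_equal(apply_feature_layer(fl$layer, X), fl$Z)
  expect_equal(fl$Z, fit_feature_layer(X, 2, 3, seed = 1)$Z)
  expect_false(isTRUE(all.equal(fl$Z, fit_feature_layer(X, 2, 3,
                                                        seed = 2)$Z)))
  one <- apply_feature_layer(fl$layer, X[1, , drop = FALSE])
  expect_equal(dim(one), c(1, 6))
  expect_true(all(abs(fl$Z) < 1))              # tanh range
  expect_error(apply_feature_layer(fl$layer, X[, 1:3]), "columns")
})

test_that("zero input with identity activation reproduces the bias rows", {
  X0 <- matrix(0, 4, 3)
  fl <- fit_feature_layer(X0, 2, 5, activation = "identity", seed = 9)
  b <- c(fl$layer$groups[[1]]$b, fl$layer$groups[[2]]$b)
  expect_equal(fl$Z, matrix(b, 4, 10, byrow = TRUE))
})

test_that("RFF basis sampling matches its stated distribution", {
  expect_error(sample_rff_basis(3, 10, sigma = 0), "sigma")
  b1 <- sample_rff_basis(1, 1e5, sigma = 1, seed = 4)
  expect_true(stats::sd(b1$W) > 0.99 && stats::sd(b1$W) < 1.01)
  b2 <- sample_rff_basis(1, 1e5, sigma = 2, seed = 4)
  expect_equal(b2$W, b1$W / 2)
  bm <- sample_rff_basis(3, 1, sigma = 1, seed = 1)
  expect_equal(ncol(rff_transform(bm, matrix(rnorm(6), 2))), 2)
})

test_that("the RFF map satisfies its trigonometric identities", {
  basis <- sample_rff_basis(4, 50, sigma = 1.3, seed = 2)
  Z <- matrix(rnorm(40), 10, 4)
  H <- rff_transform(basis, Z)
  expect_equal(dim(H), c(10, 100))
  # z = 0 maps to (1/sqrt(m), ..., 0, ...)
  H0 <- rff_transform(basis, matrix(0, 1, 4))
  expect_equal(drop(H0), c(rep(1 / sqrt(50), 50), rep(0, 50)))
  # unit row norms
  expect_equal(rowSums(H^2), rep(1, 10), tolerance = 1e-12)
  # product-to-difference identity: H_a . H_b = mean_j cos(w_j'(z_a - z_b))
  for (pair in list(c(1, 2), c(3, 7))) {
    lhs <- sum(H[pair[1], ] * H[pair[2], ])
    rhs <- mean(cos(basis$W %*% (Z[pair[1], ] - Z[pair[2], ])))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
  expect_error(rff_transform(basis, Z[, 1:3]), "columns")
})

test_that("approximate Gram behaves like a Gram matrix", {
  basis <- sample_rff_basis(3, 200, sigma = 1, seed = 5)
  Z <- matrix(rnorm(30), 10, 3)
  H <- rff_transform(basis, Z)
  Om <- approx_gram(H, H)
  expect_equal(Om, t(Om), tolerance = 1e-12)
  expect_equal(diag(Om), rep(1, 10), tolerance = 1e-12)
  expect_equal(approx_gram(H[1, , drop = FALSE], H[1, , drop = FALSE]),
               matrix(1), tolerance = 1e-12)
})

test_that("exact RBF Gram has its closed-form values", {
  Z <- rbind(c(0, 0), c(1, 0), c(3, 0))
  K <- exact_rbf_gram(Z, Z, sigma = 1)
  expect_equal(diag(K), rep(1, 3))
  # distance sigma*sqrt(2) -> exp(-1)
  Z2 <- rbind(c(0, 0), c(sqrt(2), 0))
  expect_equal(exact_rbf_gram(Z2, Z2, 1)[1, 2], exp(-1))
  expect_true(K[1, 2] > K[1, 3])               # monotone in distance
  expect_error(exact_rbf_gram(Z, Z, sigma = -1), "sigma")
})

test_that("approximation error shrinks with m and is unbiased", {
  set.seed(3)
  Z <- matrix(rnorm(25 * 4), 25, 4)
  K <- exact_rbf_gram(Z, Z, sigma = 1.5)
  err <- sapply(c(10, 100, 1000), function(m) {
    mean(sapply(1:5, function(s) {
      H <- rff_transform(sample_rff_basis(4, m, 1.5, seed = s), Z)
      mean(abs(approx_gram(H, H) - K))
    }))
  })
  expect_true(all(diff(err) < 0))
  # unbiasedness at m = 100 over 50 bases, within 3 standard errors
  ij <- cbind(c(2, 5, 11), c(17, 3, 20))
  draws <- sapply(1:50, function(s) {
    H <- rff_transform(sample_rff_basis(4, 100, 1.5, seed = 100 + s), Z)
    Om <- approx_gram(H, H)
    Om[ij]
  })
  for (r in 1:3) {
    se <- stats::sd(draws[r, ]) / sqrt(50)
    expect_lt(abs(mean(draws[r, ]) - K[ij][r]), 3 * se + 1e-12)
  }
})

test_that("kernel autoencoder solves its ridge problem", {
  set.seed(8)
  Z <- matrix(rnorm(30 * 6), 30, 6)
  Omega <- exact_rbf_gram(Z, Z, 2)
  C <- 0.01
  W <- fit_kernel_ae(Z, Omega, C)
  # push-through identity: right-sided vs normal-equations form
  W_norm <- solve(C * diag(6) + crossprod(Z), crossprod(Z, Omega))
  expect_equal(W, W_norm, tolerance = 1e-8)
  # self-reconstruction limit: Omega = Z Z', C -> 0
  for (Cs in c(1e-2, 1e-6)) {
    Wr <- fit_kernel_ae(Z, tcrossprod(Z), Cs)
    relerr <- norm(Z %*% Wr - tcrossprod(Z), "F") / norm(tcrossprod(Z), "F")
    if (Cs == 1e-6) expect_lt(relerr, 1e-6)
  }
  # regularization limit: C -> Inf kills the weights
  expect_lt(max(abs(fit_kernel_ae(Z, Omega, 1e12))), 1e-9)
  expect_error(fit_kernel_ae(Z, Omega, C = 0), "C must be")
})
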