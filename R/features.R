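# Random feature layer, random Fourier features, Gram matrices, and the
# kernel-autoencoder reconstruction weights shared by KBLS and AKBLS.

activation_fun <- function(name) {
  switch(name,
         tanh = tanh,
         sigmoid = function(x) 1 / (1 + exp(-x)),
         relu = function(x) pmax(x, 0),
         identity = identity,
         stop_bs(sprintf("unknown activation '%s'", name), "bs_bad_config"))
}

#' Fit the random feature layer of a broad learning system
#'
#' Draws `n_groups` groups of `nodes_per_group` feature nodes. Group i has a
#' weight matrix W_i (M x nodes_per_group) and a bias row b_i (1 x
#' nodes_per_group), both with entries uniform on \[-1, 1\]; its output is
#' `phi(X %*% W_i + b_i)`. The layer output Z is the column concatenation of
#' all groups (N x n_groups*nodes_per_group).
#'
#' @param X_scaled standardized input matrix (N x M).
#' @param n_groups number of feature-node groups (>= 1).
#' @param nodes_per_group nodes per group (>= 1).
#' @param activation one of `"tanh"` (default), `"sigmoid"`, `"relu"`,
#'   `"identity"`.
#' @param seed integer seed for the weight draws.
#' @return list with elements `layer` (a `feature_layer`) and `Z`.
#' @export
fit_feature_layer <- function(X_scaled, n_groups = 10, nodes_per_group = 10,
                              activation = "tanh", seed = 1) {
  X_scaled <- as.matrix(X_scaled)
  check_finite_matrix(X_scaled, "X")
  stopifnot(n_groups >= 1, nodes_per_group >= 1)
  M <- ncol(X_scaled)
  draws <- with_seed(seed, lapply(seq_len(n_groups), function(i) {
    list(W = matrix(stats::runif(M * nodes_per_group, -1, 1), M),
         b = stats::runif(nodes_per_group, -1, 1))
  }))
  layer <- structure(list(n_groups = n_groups,
                          nodes_per_group = nodes_per_group,
                          M = M, activation = activation,
                          groups = draws, seed = seed),
                     class = "feature_layer")
  list(layer = layer, Z = apply_feature_layer(layer, X_scaled))
}

#' Apply a fitted feature layer to new (standardized) data
#'
#' @param layer a `feature_layer` from [fit_feature_layer()].
#' @param X_scaled matrix with the same number of columns as at fit time.
#' @return N x (n_groups*nodes_per_group) matrix Z.
#' @export
apply_feature_layer <- function(layer, X_scaled) {
  X_scaled <- as.matrix(X_scaled)
  if (ncol(X_scaled) != layer$M) {
    stop_bs(sprintf("feature layer expects %d input columns, got %d",
                    layer$M, ncol(X_scaled)), "bs_dim_mismatch")
  }
  phi <- activation_fun(layer$activation)
  do.call(cbind, lapply(layer$groups, function(g) {
    phi(sweep(X_scaled %*% g$W, 2, g$b, "+"))
  }))
}

#' Sample a random Fourier feature basis for the RBF kernel
#'
#' Draws `m` frequency vectors i.i.d. from N(0, sigma^-2 I), the spectral
#' density of the Gaussian kernel `exp(-||x - y||^2 / (2 sigma^2))` (Bochner's
#' theorem). The induced feature map is 2m-dimensional (cosine and sine
#' parts) and every mapped point has unit Euclidean norm.
#'
#' @param dim input dimension of the map (number of feature-layer columns).
#' @param m number of Fourier components (>= 1).
#' @param sigma kernel bandwidth (> 0), in units of the mapped space.
#' @param seed integer seed.
#' @return an `rff_basis` with the m x dim frequency matrix `W`.
#' @export
sample_rff_basis <- function(dim, m, sigma, seed = 1) {
  stopifnot(m >= 1, dim >= 1)
  if (!is.numeric(sigma) || sigma <= 0) {
    stop_bs("sigma must be > 0", "bs_bad_config")
  }
  W <- with_seed(seed, matrix(stats::rnorm(m * dim, sd = 1 / sigma), m, dim))
  structure(list(m = m, dim = dim, sigma = sigma, W = W, seed = seed),
            class = "rff_basis")
}

#' Map data through a random Fourier feature basis
#'
#' Row i of the result is
#' `(cos(w_1' z_i), ..., cos(w_m' z_i), sin(w_1' z_i), ..., sin(w_m' z_i)) / sqrt(m)`,
#' so that inner products of mapped rows are Monte-Carlo estimates of the
#' RBF kernel between the original rows.
#'
#' @param basis an [sample_rff_basis()] object.
#' @param Z matrix with `basis$dim` columns.
#' @return N x 2m matrix H.
#' @export
rff_transform <- function(basis, Z) {
  Z <- as.matrix(Z)
  if (ncol(Z) != basis$dim) {
    stop_bs(sprintf("basis expects %d columns, got %d", basis$dim, ncol(Z)),
            "bs_dim_mismatch")
  }
  proj <- Z %*% t(basis$W)
  cbind(cos(proj), sin(proj)) / sqrt(basis$m)
}

#' Approximate kernel (Gram) matrix from RFF-mapped data
#'
#' The sample-by-sample Gram matrix `Omega[i, j] = H_a[i, ] . H_b[j, ]`,
#' which approximates the RBF kernel between the underlying points.
#'
#' @param H_a,H_b RFF-mapped matrices with equal column counts.
#' @return A x B matrix.
#' @export
approx_gram <- function(H_a, H_b = H_a) {
  H_a <- as.matrix(H_a); H_b <- as.matrix(H_b)
  if (ncol(H_a) != ncol(H_b)) {
    stop_bs("column counts differ", "bs_dim_mismatch")
  }
  tcrossprod(H_a, H_b)
}

#' Exact RBF (Gaussian) Gram matrix
#'
#' `K[i, j] = exp(-||Z_a[i, ] - Z_b[j, ]||^2 / (2 sigma^2))`.
#'
#' @param Z_a,Z_b matrices with equal column counts.
#' @param sigma kernel bandwidth (> 0).
#' @return A x B matrix.
#' @export
exact_rbf_gram <- function(Z_a, Z_b = Z_a, sigma) {
  if (!is.numeric(sigma) || sigma <= 0) {
    stop_bs("sigma must be > 0", "bs_bad_config")
  }
  Z_a <- as.matrix(Z_a); Z_b <- as.matrix(Z_b)
  if (ncol(Z_a) != ncol(Z_b)) {
    stop_bs("column counts differ", "bs_dim_mismatch")
  }
  d2 <- outer(rowSums(Z_a^2), rowSums(Z_b^2), "+") - 2 * tcrossprod(Z_a, Z_b)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

#' Ridge reconstruction weights from feature nodes to the kernel block
#'
#' Solves `argmin ||Z W - Omega||^2 + C ||W||^2`, the kernel-autoencoder
#' step that lets the kernel block be reproduced from feature nodes at test
#' time. The solution `W = Z' (C I + Z Z')^{-1} Omega` is computed through a
#' symmetric positive-definite Cholesky solve on whichever side (N or n_F)
#' is smaller; the two forms are equal by the push-through identity.
#'
#' @param Z feature-node matrix (N x n_F).
#' @param Omega kernel block (N x K).
#' @param C ridge constant (> 0).
#' @return n_F x K weight matrix.
#' @export
fit_kernel_ae <- function(Z, Omega, C) {
  Z <- as.matrix(Z); Omega <- as.matrix(Omega)
  stopifnot(nrow(Z) == nrow(Omega))
  if (!is.numeric(C) || C <= 0) stop_bs("C must be > 0", "bs_bad_config")
  N <- nrow(Z); nF <- ncol(Z)
  W <- if (N <= nF) {
    crossprod(Z, chol_solve(diag(C, N) + tcrossprod(Z), Omega))
  } else {
    chol_solve(diag(C, nF) + crossprod(Z), crossprod(Z, Omega))
  }
  if (!all(is.finite(W))) {
    stop_bs("kernel autoencoder solve produced non-finite weights",
            "bs_numeric_failure")
  }
  W
}

# Median-of-pairwise-distances bandwidth heuristic, computed on at most
# `max_n` evenly spaced rows so large inputs stay cheap. Deterministic.
median_heuristic <- function(Z, max_n = 400) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (n > max_n) {
    Z <- Z[unique(round(seq(1, n, length.out = max_n))), , drop = FALSE]
  }
  d <- stats::dist(Z)
  md <- stats::median(d[d > 0])
  if (!is.finite(md) || md <= 0) 1 else md
}
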