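# The three broad-learning soft-sensor estimators: BLS (random enhancement
# nodes), KBLS (exact RBF kernel block) and AKBLS (random-Fourier-feature
# approximate kernel block), with standardization, closed-form ridge output
# solving and prediction.

# ---- scaler -----------------------------------------------------------------

fit_scaler <- function(X, y = NULL, scale_target = TRUE) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  constant <- !is.finite(sd) | sd < 1e-12
  sd[constant] <- 1
  s <- list(mean = mu, sd = sd, constant = constant,
            scale_target = scale_target)
  if (!is.null(y)) {
    s$y_mean <- if (scale_target) mean(y) else 0
    s$y_sd <- if (scale_target) max(stats::sd(y), 1e-12) else 1
  }
  structure(s, class = "bs_scaler")
}

scale_inputs <- function(scaler, X) {
  sweep(sweep(as.matrix(X), 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

scale_target <- function(scaler, y) (y - scaler$y_mean) / scaler$y_sd
unscale_target <- function(scaler, ys) ys * scaler$y_sd + scaler$y_mean

# ---- output solver ----------------------------------------------------------

#' Closed-form ridge solution of the output layer
#'
#' Solves `argmin ||A W - Y||^2 + gamma ||W||^2` with the ridge-regularized
#' pseudo-inverse, `W = A' (gamma I_N + A A')^{-1} Y`, computed by a
#' symmetric positive-definite Cholesky solve on the smaller of the two
#' Gram sides (the left and right forms agree by the push-through identity).
#' At `gamma = 0` the minimum-norm least-squares solution (SVD
#' pseudo-inverse) is returned.
#'
#' @param A hidden-layer matrix (N x P).
#' @param Y target column (length N or N x 1).
#' @param gamma ridge constant (>= 0).
#' @return P x 1 weight matrix.
#' @export
solve_ridge_output <- function(A, Y, gamma) {
  A <- as.matrix(A)
  Y <- matrix(as.numeric(Y), nrow(A))
  if (!is.numeric(gamma) || gamma < 0) {
    stop_bs("gamma must be >= 0", "bs_bad_config")
  }
  if (gamma == 0) {
    return(pinv_solve(A, Y))
  }
  N <- nrow(A); P <- ncol(A)
  W <- if (N <= P) {
    crossprod(A, chol_solve(diag(gamma, N) + tcrossprod(A), Y))
  } else {
    chol_solve(diag(gamma, P) + crossprod(A), crossprod(A, Y))
  }
  if (!all(is.finite(W))) {
    message("ridge solve ill-conditioned; falling back to minimum-norm solution")
    W <- pinv_solve(A, Y)
  }
  W
}

# ---- model configuration ----------------------------------------------------

#' Configuration of a broad-learning soft-sensor model
#'
#' @param mode `"akbls"` (approximate kernel, default), `"kbls"` (exact RBF
#'   kernel) or `"bls"` (random enhancement nodes).
#' @param n_groups feature-node groups.
#' @param nodes_per_group nodes per group.
#' @param activation feature-layer activation.
#' @param m_fourier number of random Fourier components (akbls).
#' @param sigma RBF bandwidth on the feature-layer scale; `NULL` (default)
#'   selects the median pairwise distance of the training feature nodes.
#' @param sigma_scale multiplier applied to the median-heuristic bandwidth
#'   (ignored when `sigma` is given).
#' @param C ridge constant of the kernel-autoencoder reconstruction.
#' @param gamma ridge constant of the output layer.
#' @param n_enhance enhancement nodes (bls mode).
#' @param enhance_activation enhancement activation (bls mode).
#' @param test_kernel how kernel columns are built at test time:
#'   `"direct"` (default; cross-Gram of the new samples against the stored
#'   training features, the mapping that preserves the kernel block's
#'   capacity out of sample) or `"ae"` (reconstruct the kernel columns from
#'   the feature nodes through the autoencoder weights W_Omega — this is
#'   linear in the feature layer and is kept as an ablation switch).
#' @param scale_targets standardize the target during fitting (default TRUE).
#' @param seed master seed of all random structures.
#' @return a `model_config` list.
#' @export
model_config <- function(mode = c("akbls", "kbls", "bls"), n_groups = 10,
                         nodes_per_group = 10, activation = "tanh",
                         m_fourier = 500, sigma = NULL, sigma_scale = 1,
                         C = 1e-6, gamma = 1e-6, n_enhance = 100,
                         enhance_activation = "tanh",
                         test_kernel = c("direct", "ae"),
                         scale_targets = TRUE, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_groups >= 1, nodes_per_group >= 1, m_fourier >= 1,
            C > 0, gamma >= 0, n_enhance >= 1, sigma_scale > 0)
  if (!is.null(sigma) && (!is.numeric(sigma) || sigma <= 0)) {
    stop_bs("sigma must be > 0 (or NULL for the median heuristic)",
            "bs_bad_config")
  }
  structure(list(mode = mode, n_groups = n_groups,
                 nodes_per_group = nodes_per_group, activation = activation,
                 m_fourier = m_fourier, sigma = sigma,
                 sigma_scale = sigma_scale, C = C, gamma = gamma,
                 n_enhance = n_enhance,
                 enhance_activation = enhance_activation,
                 test_kernel = match.arg(test_kernel),
                 scale_targets = scale_targets, seed = seed),
            class = "model_config")
}

# ---- fitting ----------------------------------------------------------------

#' Fit a broad-learning soft-sensor model
#'
#' Pipeline: standardize inputs (and target) -> random feature layer ->
#' hidden block (approximate kernel Gram for akbls, exact RBF Gram for
#' kbls, random enhancement nodes for bls) -> hidden layer `A = [Z, block]`
#' -> closed-form ridge output weights. All randomness derives from
#' `config$seed`.
#'
#' @param data a [process_dataset()], or any list with elements `X` and `y`.
#' @param config a [model_config()].
#' @return a `soft_sensor_model`.
#' @export
fit_model <- function(data, config = model_config()) {
  X <- as.matrix(data$X); y <- as.numeric(data$y)
  if (nrow(X) < 2) stop_bs("need at least 2 training samples", "bs_bad_data")
  check_finite_matrix(X, "X"); check_finite_matrix(y, "y")
  stopifnot(inherits(config, "model_config"))

  scaler <- fit_scaler(X, y, scale_target = config$scale_targets)
  Xs <- scale_inputs(scaler, X)
  ys <- scale_target(scaler, y)

  fl <- fit_feature_layer(Xs, config$n_groups, config$nodes_per_group,
                          config$activation, seed = config$seed)
  Z <- fl$Z

  kernel <- NULL; enhance <- NULL
  if (config$mode == "bls") {
    nF <- ncol(Z)
    enh <- with_seed(derive_seed(config$seed, 2), list(
      W = matrix(stats::runif(nF * config$n_enhance, -1, 1), nF),
      b = stats::runif(config$n_enhance, -1, 1)
    ))
    enh$activation <- config$enhance_activation
    block <- activation_fun(enh$activation)(
      sweep(Z %*% enh$W, 2, enh$b, "+"))
    enhance <- enh
  } else {
    sigma <- config$sigma %||% (config$sigma_scale * median_heuristic(Z))
    if (config$mode == "akbls") {
      basis <- sample_rff_basis(ncol(Z), config$m_fourier, sigma,
                                seed = derive_seed(config$seed, 3))
      H <- rff_transform(basis, Z)
      Omega <- approx_gram(H, H)
      kernel <- list(type = "approximate", basis = basis, H_train = H)
    } else {
      Omega <- exact_rbf_gram(Z, Z, sigma)
      kernel <- list(type = "exact", Z_train = Z)
    }
    kernel$sigma <- sigma
    kernel$W_Omega <- fit_kernel_ae(Z, Omega, config$C)
    block <- Omega
  }

  A <- cbind(Z, block)
  W <- solve_ridge_output(A, ys, config$gamma)

  structure(list(mode = config$mode, config = config, scaler = scaler,
                 layer = fl$layer, kernel = kernel, enhance = enhance,
                 W = W, n_train = nrow(X),
                 variables = colnames(X) %||% paste0("x", seq_len(ncol(X)))),
            class = "soft_sensor_model")
}

#' @export
print.soft_sensor_model <- function(x, ...) {
  cat(sprintf("<soft_sensor_model> mode=%s, trained on %d samples x %d vars\n",
              x$mode, x$n_train, length(x$variables)))
  invisible(x)
}

# Hidden-layer matrix for new (already standardized) inputs.
model_hidden <- function(model, Xs) {
  Z <- apply_feature_layer(model$layer, Xs)
  block <- if (model$mode == "bls") {
    activation_fun(model$enhance$activation)(
      sweep(Z %*% model$enhance$W, 2, model$enhance$b, "+"))
  } else if (model$config$test_kernel == "ae") {
    Z %*% model$kernel$W_Omega
  } else if (model$mode == "akbls") {
    approx_gram(rff_transform(model$kernel$basis, Z), model$kernel$H_train)
  } else {
    exact_rbf_gram(Z, model$kernel$Z_train, model$kernel$sigma)
  }
  cbind(Z, block)
}

#' Predict with a fitted soft-sensor model
#'
#' @param object a `soft_sensor_model`.
#' @param newdata a [process_dataset()], matrix or data frame whose columns
#'   match the training variables.
#' @param ... ignored.
#' @return numeric vector of predictions on the original target scale.
#' @export
predict.soft_sensor_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "process_dataset")) newdata$X else
    as.matrix(newdata)
  if (!is.null(colnames(X))) {
    missing <- setdiff(object$variables, colnames(X))
    extra <- setdiff(colnames(X), object$variables)
    if (length(missing) || length(extra)) {
      stop_bs(sprintf("column mismatch: missing [%s], extra [%s]",
                      paste(missing, collapse = ", "),
                      paste(extra, collapse = ", ")), "bs_dim_mismatch")
    }
    X <- X[, object$variables, drop = FALSE]
  } else if (ncol(X) != length(object$variables)) {
    stop_bs(sprintf("expected %d columns, got %d", length(object$variables),
                    ncol(X)), "bs_dim_mismatch")
  }
  Xs <- scale_inputs(object$scaler, X)
  A <- model_hidden(object, Xs)
  drop(unscale_target(object$scaler, A %*% object$W))
}

# ---- persistence ------------------------------------------------------------

# Numeric payloads are stored as C99 hexadecimal float strings so that a
# load/save round trip is bit-exact (decimal JSON numbers are not).
ser_num <- function(x) sprintf("%a", as.numeric(x))
deser_num <- function(s) {
  out <- as.numeric(unlist(s))
  names(out) <- names(unlist(s))
  out
}
ser_mat <- function(m) list(data = ser_num(m), nrow = nrow(m),
                            ncol = ncol(m))
deser_mat <- function(s) matrix(deser_num(s$data), s$nrow, s$ncol)

#' Save a fitted soft-sensor model to a JSON archive
#'
#' The archive holds the resolved configuration, scaler statistics, every
#' weight matrix and all seeds at full floating-point precision, so that
#' loading reproduces the saved session's predictions exactly.
#'
#' @param model a `soft_sensor_model`.
#' @param path output file.
#' @export
save_model <- function(model, path) {
  obj <- list(
    format = "broadsensor-model-1",
    mode = model$mode,
    config = unclass(model$config),
    variables = model$variables,
    n_train = model$n_train,
    scaler = list(mean = ser_num(model$scaler$mean),
                  sd = ser_num(model$scaler$sd),
                  constant = model$scaler$constant,
                  scale_target = model$scaler$scale_target,
                  y_mean = ser_num(model$scaler$y_mean),
                  y_sd = ser_num(model$scaler$y_sd)),
    layer = list(n_groups = model$layer$n_groups,
                 nodes_per_group = model$layer$nodes_per_group,
                 M = model$layer$M, activation = model$layer$activation,
                 seed = model$layer$seed,
                 groups = lapply(model$layer$groups, function(g)
                   list(W = ser_mat(g$W), b = ser_num(g$b)))),
    W = ser_num(model$W)
  )
  if (!is.null(model$kernel)) {
    k <- model$kernel
    obj$kernel <- list(type = k$type, sigma = ser_num(k$sigma),
                       W_Omega = ser_mat(k$W_Omega))
    if (k$type == "approximate") {
      obj$kernel$basis <- list(m = k$basis$m, dim = k$basis$dim,
                               sigma = ser_num(k$basis$sigma),
                               seed = k$basis$seed,
                               W = ser_mat(k$basis$W))
      obj$kernel$H_train <- ser_mat(k$H_train)
    } else {
      obj$kernel$Z_train <- ser_mat(k$Z_train)
    }
  }
  if (!is.null(model$enhance)) {
    obj$enhance <- list(W = ser_mat(model$enhance$W),
                        b = ser_num(model$enhance$b),
                        activation = model$enhance$activation)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a soft-sensor model saved by [save_model()]
#'
#' @param path JSON archive path.
#' @return a `soft_sensor_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(obj$format, "broadsensor-model-1")) {
    stop_bs("not a broadsensor model archive (or unsupported version)",
            "bs_bad_data")
  }
  cfg <- obj$config
  cfg$sigma <- cfg$sigma %||% NULL
  config <- structure(cfg, class = "model_config")
  scaler <- structure(list(mean = deser_num(obj$scaler$mean),
                           sd = deser_num(obj$scaler$sd),
                           constant = obj$scaler$constant,
                           scale_target = obj$scaler$scale_target,
                           y_mean = deser_num(obj$scaler$y_mean),
                           y_sd = deser_num(obj$scaler$y_sd)),
                      class = "bs_scaler")
  groups <- lapply(obj$layer$groups, function(g)
    list(W = deser_mat(g$W), b = deser_num(g$b)))
  layer <- structure(list(n_groups = obj$layer$n_groups,
                          nodes_per_group = obj$layer$nodes_per_group,
                          M = obj$layer$M,
                          activation = obj$layer$activation,
                          groups = groups, seed = obj$layer$seed),
                     class = "feature_layer")
  kernel <- NULL
  if (!is.null(obj$kernel)) {
    kernel <- list(type = obj$kernel$type,
                   sigma = deser_num(obj$kernel$sigma),
                   W_Omega = deser_mat(obj$kernel$W_Omega))
    if (kernel$type == "approximate") {
      b <- obj$kernel$basis
      kernel$basis <- structure(list(m = b$m, dim = b$dim, sigma = deser_num(b$sigma),
                                     W = deser_mat(b$W), seed = b$seed),
                                class = "rff_basis")
      kernel$H_train <- deser_mat(obj$kernel$H_train)
    } else {
      kernel$Z_train <- deser_mat(obj$kernel$Z_train)
    }
  }
  enhance <- NULL
  if (!is.null(obj$enhance)) {
    enhance <- list(W = deser_mat(obj$enhance$W), b = deser_num(obj$enhance$b),
                    activation = obj$enhance$activation)
  }
  structure(list(mode = obj$mode, config = config, scaler = scaler,
                 layer = layer, kernel = kernel, enhance = enhance,
                 W = matrix(deser_num(obj$W)), n_train = obj$n_train,
                 variables = obj$variables),
            class = "soft_sensor_model")
}
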