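# Shared fixtures. Heavy simulated objects are memoized in this environment
# so several test files can reuse them within one test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Smooth nonlinear toy regression problem: y = sin(3 x1) + x2^2 (+ 0.5 x3
# when a third column exists). Two input dimensions by default: at these
# sample sizes the function is densely sampled, so kernel methods can be
# expected to recover it nearly exactly.
make_toy_data <- function(n = 100, p = 2, seed = 1, noise_sd = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  y <- sin(3 * X[, 1]) + X[, 2]^2 + (if (p >= 3) 0.5 * X[, 3] else 0) +
    if (noise_sd > 0) rnorm(n, sd = noise_sd) else 0
  process_dataset(X, y)
}

# One short simulated batch, reused across files.
short_batch <- function() {
  cached("short_batch",
         simulate_batch(batch_config(duration_h = 120), batch_id = "b1"))
}

# Reduced drifting campaign for ensemble/window tests: 4 training batches of
# 150 h plus one test batch started outside the training envelope.
small_campaign <- function() {
  cached("small_campaign", {
    base <- batch_config(duration_h = 150)
    train <- simulate_campaign(4, base,
                               variation = c(substrate = 0.05,
                                             biomass = 0.05, volume = 0.03),
                               seed = 11)
    cfg <- base
    cfg$substrate0 <- base$substrate0 * 1.2
    test <- simulate_batch(cfg, batch_id = "batch_test")
    list(train = train, test = test)
  })
}

# ---- literal dense-algebra oracle -------------------------------------------
# Recomputes predictions of a fitted model by transcribing the defining
# equations with explicit dense inverses (solve()), sharing only the fitted
# random structures (feature layer, Fourier basis, enhancement weights).

oracle_predict <- function(model, X_train, y_train, X_test) {
  act <- function(name) switch(name, tanh = tanh,
                               sigmoid = function(x) 1 / (1 + exp(-x)),
                               relu = function(x) pmax(x, 0),
                               identity = identity)
  phi <- act(model$layer$activation)
  sc <- model$scaler
  std <- function(X) sweep(sweep(X, 2, sc$mean, "-"), 2, sc$sd, "/")
  Xs <- std(X_train); Xs_new <- std(X_test)
  ys <- (y_train - sc$y_mean) / sc$y_sd

  layer_of <- function(Xm) {
    out <- NULL
    for (g in model$layer$groups) {
      Zi <- phi(Xm %*% g$W + matrix(g$b, nrow(Xm), length(g$b), byrow = TRUE))
      out <- cbind(out, Zi)
    }
    out
  }
  Z <- layer_of(Xs); Z_new <- layer_of(Xs_new)
  C <- model$config$C; gam <- model$config$gamma
  N <- nrow(Z)

  if (model$mode == "bls") {
    e <- model$enhance
    eact <- act(e$activation)
    block <- eact(Z %*% e$W + matrix(e$b, N, length(e$b), byrow = TRUE))
    block_new <- eact(Z_new %*% e$W +
                        matrix(e$b, nrow(Z_new), length(e$b), byrow = TRUE))
  } else {
    if (model$mode == "akbls") {
      B <- model$kernel$basis
      rff <- function(Zm) {
        pr <- Zm %*% t(B$W)
        cbind(cos(pr), sin(pr)) / sqrt(B$m)
      }
      H <- rff(Z)
      Omega <- H %*% t(H)
    } else {
      sg <- model$kernel$sigma
      gram <- function(A, B2) {
        K <- matrix(0, nrow(A), nrow(B2))
        for (i in seq_len(nrow(A)))
          for (j in seq_len(nrow(B2)))
            K[i, j] <- exp(-sum((A[i, ] - B2[j, ])^2) / (2 * sg^2))
        K
      }
      Omega <- gram(Z, Z)
    }
    W_Omega <- t(Z) %*% solve(C * diag(N) + Z %*% t(Z)) %*% Omega
    block <- Omega
    block_new <- Z_new %*% W_Omega          # AE reconstruction at test time
  }
  A <- cbind(Z, block)
  W <- t(A) %*% solve(gam * diag(N) + A %*% t(A)) %*% matrix(ys)
  A_new <- cbind(Z_new, block_new)
  drop(A_new %*% W) * sc$y_sd + sc$y_mean
}
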