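# Soft-sensor models: output solver identities, fitting, prediction,
# invariants and persistence.

test_that("ridge output solver matches its closed forms", {
  # identity design, gamma = 0 -> W = Y
  Y <- c(1, -2, 3)
  expect_equal(drop(solve_ridge_output(diag(3), Y, 0)), Y)
  # push-through identity against the normal-equations oracle
  set.seed(2)
  A <- matrix(rnorm(100), 20, 5); Y <- matrix(rnorm(20))
  W <- solve_ridge_output(A, Y, 0.1)
  W_oracle <- solve(crossprod(A) + 0.1 * diag(5), crossprod(A, Y))
  expect_equal(W, W_oracle, tolerance = 1e-8)
  # and for the wide case (N < P), where the right-sided branch is taken
  Aw <- matrix(rnorm(100), 5, 20); Yw <- matrix(rnorm(5))
  expect_equal(solve_ridge_output(Aw, Yw, 0.1),
               solve(crossprod(Aw) + 0.1 * diag(20), crossprod(Aw, Yw)),
               tolerance = 1e-8)
  expect_equal(drop(solve_ridge_output(A, rep(0, 20), 0.5)), rep(0, 5))
  expect_error(solve_ridge_output(A, Y, -1), "gamma")
})

test_that("akbls recovers a smooth nonlinear function", {
  train <- make_toy_data(500, seed = 10)
  test <- make_toy_data(300, seed = 11)
  m <- fit_model(train, model_config("akbls", seed = 1))
  expect_gt(r2_score(test$y, predict(m, test$X)), 0.99)
})

test_that("akbls converges to kbls as the Fourier expansion grows", {
  train <- make_toy_data(200, seed = 20)
  test <- make_toy_data(150, seed = 21)
  sig <- 5   # shared fixed bandwidth so only the kernel approximation differs
  pk <- predict(fit_model(train, model_config("kbls", sigma = sig, seed = 3)),
                test$X)
  pa <- predict(fit_model(train, model_config("akbls", sigma = sig,
                                              m_fourier = 1e4, seed = 3)),
                test$X)
  expect_lt(rmse(pk, pa) / stats::sd(train$y), 0.05)
})

test_that("degenerate targets and training-set interpolation behave", {
  train <- make_toy_data(80, seed = 30)
  const <- process_dataset(train$X, rep(4.2, 80))
  m <- fit_model(const, model_config("akbls", seed = 1))
  expect_equal(predict(m, train$X), rep(4.2, 80), tolerance = 1e-6)
  for (mode in c("akbls", "kbls")) {
    mi <- fit_model(train, model_config(mode, gamma = 1e-10, C = 1e-8,
                                        seed = 2))
    expect_gte(r2_score(train$y, predict(mi, train$X)), 0.999)
  }
})

test_that("predictions are equivariant under training-row permutation", {
  train <- make_toy_data(60, seed = 40)
  test <- make_toy_data(20, seed = 41)
  perm <- with(list(), {set.seed(5); sample(60)})
  for (mode in c("akbls", "kbls", "bls")) {
    cfg <- model_config(mode, seed = 6)
    p1 <- predict(fit_model(train, cfg), test$X)
    p2 <- predict(fit_model(train[perm], cfg), test$X)
    expect_equal(p1, p2, tolerance = 1e-8)
  }
})

test_that("training error is monotone in capacity and in gamma", {
  train <- make_toy_data(150, seed = 50)
  # capacity: more feature nodes per group -> training RMSE non-increasing
  rmses <- sapply(c(2, 8, 32), function(nf) {
    m <- fit_model(train, model_config("bls", nodes_per_group = nf,
                                       gamma = 1e-8, seed = 7))
    rmse(train$y, predict(m, train$X))
  })
  expect_true(all(diff(rmses) <= 1e-8))
  # gamma: residual shrinks to 0 and the weight norm never grows
  gammas <- c(1, 1e-2, 1e-4, 1e-8)
  fits <- lapply(gammas, function(g)
    fit_model(train, model_config("akbls", gamma = g, seed = 7)))
  res <- sapply(fits, function(m) rmse(train$y, predict(m, train$X)))
  wnorm <- sapply(fits, function(m) sqrt(sum(m$W^2)))
  expect_true(all(diff(res) < 0))
  expect_lt(res[length(res)], 1e-3)
  expect_true(all(diff(rev(wnorm)) <= 1e-8))   # larger gamma, smaller norm
})

test_that("prediction validates its input columns", {
  train <- make_toy_data(50, seed = 60)
  m <- fit_model(train, model_config("akbls", seed = 1))
  bad <- train$X; colnames(bad)[2] <- "zz"
  expect_error(predict(m, bad), "missing \\[x2\\], extra \\[zz\\]")
  expect_length(predict(m, train$X[1, , drop = FALSE]), 1)
})

test_that("a saved model reproduces its predictions exactly after loading", {
  train <- make_toy_data(60, seed = 70)
  test <- make_toy_data(25, seed = 71)
  f <- withr::local_tempfile(fileext = ".json")
  for (mode in c("akbls", "kbls", "bls")) {
    m <- fit_model(train, model_config(mode, seed = 9))
    p <- predict(m, test$X)
    save_model(m, f)
    m2 <- load_model(f)
    expect_identical(predict(m2, test$X), p)
  }
})

test_that("gpr meta-learner component fits smooth, gently nonlinear maps", {
  # the meta-learner is deliberately conservative (length-scale and noise
  # floors), so the contract is a good fit of near-linear maps with mild
  # curvature, not of high-frequency structure
  set.seed(12)
  X <- matrix(runif(200, -2, 2), 100, 2)
  y <- 3 + X[, 1] + 0.5 * sin(X[, 2])
  g <- fit_gpr(X, y, seed = 1)
  Xn <- matrix(runif(100, -2, 2), 50, 2)
  yn <- 3 + Xn[, 1] + 0.5 * sin(Xn[, 2])
  expect_gt(r2_score(yn, predict(g, Xn)), 0.97)
  # subsampling cap still yields a usable model
  g2 <- fit_gpr(X, y, max_points = 40, seed = 2)
  expect_gt(r2_score(yn, predict(g2, Xn)), 0.95)
})
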