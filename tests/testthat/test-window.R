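# Moving-window bookkeeping and the adaptive loop.

test_that("window slicing follows the closed-interval indexing", {
  db <- make_toy_data(200, seed = 1)
  w0 <- window_slice(db, m = 0, w_m = 100, l = 10)
  expect_equal(nrow(w0$X), 101)                 # rows 0..100 inclusive
  expect_equal(w0$X, db$X[1:101, ])
  w2 <- window_slice(db, m = 2, w_m = 100, l = 10)
  expect_equal(w2$X, db$X[21:121, ])            # rows 20..120
  # last valid window, then exhaustion
  m_max <- (200 - 1 - 100) / 10                 # m*l + w_m = n - 1
  ok <- window_slice(db, m_max, 100, 10)
  expect_equal(nrow(ok$X), 101)
  expect_error(window_slice(db, m_max + 1, 100, 10),
               class = "bs_window_exhausted")
  expect_error(window_slice(db, -1, 100, 10), class = "bs_window_invalid")
  expect_error(window_slice(db, 30, 100, 10), class = "bs_window_invalid")
})

test_that("a single-step run equals static stacking", {
  train <- make_toy_data(120, seed = 2)
  test <- make_toy_data(40, seed = 3)
  cfg <- stack_config(base = model_config("akbls", m_fourier = 100, seed = 4),
                      seed = 4)
  run <- run_mw_stacking(train, test, w_m = 119, l = 40, cfg,
                         feedback = "none")
  expect_equal(run$overall$n_windows, 1)
  # replicate the window-0 seed derivation and compare
  wcfg <- cfg
  wcfg$base_configs <- lapply(cfg$base_configs, function(bc) {
    bc$seed <- broadsensor:::derive_seed(bc$seed, 1000)
    bc
  })
  wcfg$seed <- broadsensor:::derive_seed(cfg$seed, 1000)
  sm <- fit_stacking(train[1:120], wcfg)
  expect_equal(run$predictions, predict(sm, test$X), tolerance = 1e-12)
})

test_that("window accounting: floor(test/l) models, every row predicted once", {
  train <- make_toy_data(150, seed = 5)
  test <- make_toy_data(100, seed = 6)   # 5 chunks of 20
  cfg <- model_config("akbls", m_fourier = 50, seed = 7)
  run <- run_mw_model(train, test, w_m = 100, l = 20, cfg,
                      feedback = "predicted")
  expect_equal(run$overall$n_windows, 5)
  expect_equal(nrow(run$per_window), 5)
  expect_length(run$predictions, 100)
  expect_true(all(is.finite(run$predictions)))
  # a partial final chunk is predicted by the last model
  test2 <- make_toy_data(110, seed = 8)
  run2 <- run_mw_model(train, test2, w_m = 100, l = 20, cfg)
  expect_equal(run2$overall$n_windows, 5)
  expect_length(run2$predictions, 110)
  expect_equal(run2$per_window$test_to[5], 110)
})

test_that("the full adaptive run is reproducible from the master seed", {
  train <- make_toy_data(130, seed = 9)
  test <- make_toy_data(60, seed = 10)
  cfg <- stack_config(base = model_config("akbls", m_fourier = 50, seed = 11),
                      seed = 11)
  r1 <- run_mw_stacking(train, test, w_m = 100, l = 30, cfg)
  r2 <- run_mw_stacking(train, test, w_m = 100, l = 30, cfg)
  expect_identical(r1$predictions, r2$predictions)
})

test_that("oversized windows and undersized streams are rejected", {
  train <- make_toy_data(50, seed = 12)
  test <- make_toy_data(30, seed = 13)
  expect_error(run_mw_model(train, test, w_m = 50, l = 10),
               class = "bs_window_invalid")
  expect_error(run_mw_model(train, test[1:5], w_m = 30, l = 10),
               class = "bs_bad_data")
})
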