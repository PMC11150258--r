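# Moving-window adaptive modelling: a fixed-length window slides through the
# (growing) training database as new test chunks arrive, and a fresh model is
# trained per window.

#' Slice the m-th moving window out of a database
#'
#' Window m covers database rows `m*l` through `m*l + w_m` inclusive
#' (0-based), i.e. `w_m + 1` samples.
#'
#' @param db a [process_dataset()].
#' @param m window index, starting at 0.
#' @param w_m window length parameter (the window holds `w_m + 1` rows).
#' @param l step size in samples (>= 1).
#' @return the window as a [process_dataset()].
#' @export
window_slice <- function(db, m, w_m, l) {
  n <- nrow(db$X)
  if (m < 0 || l < 1 || w_m < 1) {
    stop_bs("invalid window parameters (need m >= 0, l >= 1, w_m >= 1)",
            "bs_window_invalid")
  }
  start <- m * l + 1
  end <- m * l + w_m + 1
  if (start > n) {
    stop_bs(sprintf("window %g is invalid: start row %g beyond database (%g rows)",
                    m, start, n), "bs_window_invalid")
  }
  if (end > n) {
    stop_bs(sprintf("window %g exhausted: needs rows up to %g, database has %g",
                    m, end, n), "bs_window_exhausted")
  }
  db[start:end]
}

# Shared moving-window loop. fit_fun(dataset) -> model,
# predict_fun(model, X) -> numeric. Consumes the test stream in chunks of l
# rows (the final partial chunk is predicted with the last model), appends
# feedback rows to the database and advances the window by l.
run_mw_loop <- function(train_db, test_stream, w_m, l, fit_fun, predict_fun,
                        feedback = c("predicted", "true", "none")) {
  feedback <- match.arg(feedback)
  n_train <- nrow(train_db$X)
  n_test <- nrow(test_stream$X)
  if (n_train < w_m + 1) {
    stop_bs(sprintf("window length %d + 1 exceeds training database (%d rows)",
                    w_m, n_train), "bs_window_invalid")
  }
  if (n_test < l) stop_bs("test stream shorter than one step", "bs_bad_data")

  db <- train_db
  n_windows <- floor(n_test / l)
  preds <- numeric(n_test)
  win_rows <- vector("list", n_windows)
  y_sd <- stats::sd(test_stream$y)

  for (i in seq_len(n_windows) - 1L) {
    win <- window_slice(db, i, w_m, l)
    model <- fit_fun(win, i)
    from <- i * l + 1
    to <- if (i == n_windows - 1L) n_test else (i + 1L) * l
    chunk <- test_stream[from:to]
    p <- predict_fun(model, chunk$X)
    preds[from:to] <- p
    r2w <- if (to - from >= 1 && stats::sd(chunk$y) > 0) {
      r2_score(chunk$y, p)
    } else NA_real_
    win_rows[[i + 1L]] <- data.frame(
      window_index = i, train_rows = nrow(win$X), test_from = from,
      test_to = to, r2 = r2w, rmse = rmse(chunk$y, p),
      rmse_std = rmse(chunk$y, p) / max(y_sd, 1e-12))
    if (feedback != "none") {
      fb <- chunk
      if (feedback == "predicted") fb$y <- p
      db <- combine_datasets(db, fb)
    }
  }
  per_window <- do.call(rbind, win_rows)
  list(predictions = preds,
       per_window = per_window,
       overall = list(r2 = r2_score(test_stream$y, preds),
                      rmse = rmse(test_stream$y, preds),
                      rmse_std = rmse(test_stream$y, preds) / max(y_sd, 1e-12),
                      n_test = n_test, n_windows = n_windows,
                      feedback = feedback, w_m = w_m, l = l))
}

#' Run the moving-window stacking soft sensor
#'
#' The adaptive driver: slice the current window from the training database,
#' fit a stacking ensemble on it, predict the next `l` test rows, merge the
#' feedback rows back into the database, advance the window by `l`, and
#' repeat until the test stream is exhausted (a final partial chunk is
#' predicted with the last model).
#'
#' @param train_db training database, a [process_dataset()] of at least
#'   `w_m + 1` rows in time order.
#' @param test_stream test samples in arrival order.
#' @param w_m window length parameter (window holds `w_m + 1` samples).
#' @param l step size: rows consumed (and window advance) per iteration.
#' @param cfg a [stack_config()]; each window derives its own seed from it.
#' @param feedback what is appended to the database after predicting a
#'   chunk: `"predicted"` (default; the model's own outputs, as in
#'   self-labelled online operation), `"true"` (delayed true labels) or
#'   `"none"`.
#' @return list with `predictions` (aligned to the test stream),
#'   `per_window` metrics data frame, and `overall` metrics.
#' @export
run_mw_stacking <- function(train_db, test_stream, w_m = 2400, l = 100,
                            cfg = stack_config(),
                            feedback = c("predicted", "true", "none")) {
  run_mw_loop(train_db, test_stream, w_m, l,
              fit_fun = function(win, i) {
                wcfg <- cfg
                wcfg$seed <- derive_seed(cfg$seed, 1000 + i)
                wcfg$base_configs <- lapply(cfg$base_configs, function(bc) {
                  bc$seed <- derive_seed(bc$seed, 1000 + i)
                  bc
                })
                fit_stacking(win, wcfg)
              },
              predict_fun = function(model, X) predict(model, X),
              feedback = match.arg(feedback))
}

#' Run a moving-window loop around a single soft-sensor model
#'
#' Same adaptive loop as [run_mw_stacking()] but retraining one
#' [fit_model()] per window instead of a stacking ensemble; used by the
#' framework-ablation experiments.
#'
#' @inheritParams run_mw_stacking
#' @param config a [model_config()].
#' @return as [run_mw_stacking()].
#' @export
run_mw_model <- function(train_db, test_stream, w_m = 2400, l = 100,
                         config = model_config(),
                         feedback = c("predicted", "true", "none")) {
  run_mw_loop(train_db, test_stream, w_m, l,
              fit_fun = function(win, i) {
                wcfg <- config
                wcfg$seed <- derive_seed(config$seed, 1000 + i)
                fit_model(win, wcfg)
              },
              predict_fun = function(model, X) predict(model, X),
              feedback = match.arg(feedback))
}
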