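# Cross-validated hyperparameter search.

#' Split a dataset into train and test parts
#'
#' @param data a [process_dataset()].
#' @param frac training fraction.
#' @param seed integer seed of the random split.
#' @param by_batch if `TRUE`, whole batches are assigned to one side.
#' @return list with `train` and `test` datasets.
#' @export
train_test_split <- function(data, frac = 0.8, seed = 1, by_batch = FALSE) {
  n <- nrow(data$X)
  if (by_batch) {
    ids <- unique(data$batch_id)
    ntr <- max(1, round(frac * length(ids)))
    tr_ids <- with_seed(seed, sample(ids, ntr))
    tr <- data$batch_id %in% tr_ids
  } else {
    tr <- logical(n)
    tr[with_seed(seed, sample.int(n, max(1, round(frac * n))))] <- TRUE
  }
  list(train = data[which(tr)], test = data[which(!tr)])
}

#' Cross-validated grid search over model hyperparameters
#'
#' Exhaustive search over the Cartesian product of the supplied candidate
#' lists (any [model_config()] argument may be a grid dimension, e.g.
#' `n_groups`, `nodes_per_group`, `m_fourier`, `sigma_scale`, `C`, `gamma`).
#' Each cell is scored by k-fold cross validation (seeded shuffled folds);
#' cells that fail to fit are excluded and reported. Score ties are broken
#' towards smaller `m_fourier`, then smaller `nodes_per_group`, then the
#' earlier-listed cell.
#'
#' @param data a [process_dataset()] (the training portion only).
#' @param mode model mode passed to [model_config()].
#' @param grid named list of candidate vectors.
#' @param folds number of CV folds (default 5).
#' @param metric `"r2"` (maximized, default) or `"rmse"` (minimized).
#' @param seed integer seed (fold assignment and model seeds).
#' @return list with `best_config` (a [model_config()]), `best_cell`
#'   (named list) and `table` (per-cell mean CV scores).
#' @export
cv_grid_search <- function(data, mode = "akbls", grid = list(),
                           folds = 5, metric = c("r2", "rmse"), seed = 1) {
  metric <- match.arg(metric)
  n <- nrow(data$X)
  if (n < folds) stop_bs("fewer samples than folds", "bs_bad_data")
  cells <- if (length(grid)) {
    do.call(expand.grid, c(grid, stringsAsFactors = FALSE))
  } else data.frame(row.names = 1)
  fold <- make_folds(n, folds, shuffle = TRUE, seed = derive_seed(seed, 11))

  scores <- rep(NA_real_, max(nrow(cells), 1))
  for (ci in seq_len(max(nrow(cells), 1))) {
    args <- if (nrow(cells)) as.list(cells[ci, , drop = FALSE]) else list()
    cfg <- tryCatch(
      do.call(model_config, c(list(mode = mode, seed = derive_seed(seed, 50)),
                              args)),
      error = function(e) NULL)
    if (is.null(cfg)) {
      message(sprintf("grid cell %d invalid, excluded", ci))
      next
    }
    vals <- numeric(folds)
    ok <- TRUE
    for (f in seq_len(folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      res <- tryCatch({
        m <- fit_model(data[tr], cfg)
        p <- predict(m, data$X[te, , drop = FALSE])
        if (metric == "r2") r2_score(data$y[te], p) else rmse(data$y[te], p)
      }, error = function(e) NA_real_)
      if (is.na(res)) { ok <- FALSE; break }
      vals[f] <- res
    }
    if (!ok) {
      message(sprintf("grid cell %d failed to fit, excluded", ci))
      next
    }
    scores[ci] <- mean(vals)
  }
  if (all(is.na(scores))) {
    stop_bs("every grid cell failed", "bs_numeric_failure")
  }
  tab <- cbind(if (nrow(cells)) cells else data.frame(default = TRUE),
               score = scores)
  ord_score <- if (metric == "r2") -scores else scores
  m_col <- if ("m_fourier" %in% names(cells)) cells$m_fourier else
    rep(0, length(scores))
  nf_col <- if ("nodes_per_group" %in% names(cells)) cells$nodes_per_group
  else rep(0, length(scores))
  best <- order(ord_score, m_col, nf_col, seq_along(scores))[1]
  args <- if (nrow(cells)) as.list(cells[best, , drop = FALSE]) else list()
  best_config <- do.call(model_config,
                         c(list(mode = mode, seed = seed), args))
  list(best_config = best_config, best_cell = args, table = tab)
}
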