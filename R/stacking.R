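# Stacking ensemble: three broad-learning primary learners whose
# out-of-fold predictions feed a Gaussian-process meta-learner.

#' Configuration of a stacking ensemble
#'
#' By default three AKBLS primary learners are derived from `base`: each
#' gets its own seed and a +/-25% perturbation of nodes-per-group, Fourier
#' components and bandwidth scale around the base values, so that the bases
#' make decorrelated errors.
#'
#' @param base template [model_config()] for the primary learners.
#' @param base_configs optional explicit list of primary-learner configs
#'   (overrides `base`); the default count of three is the package's
#'   standing choice and deviations are reported when fitting.
#' @param k_folds folds used to build out-of-fold meta-features (>= 2).
#' @param meta meta-learner kind: `"gpr"` (default) or `"linear"`.
#' @param gpr_max_points training-point cap of the GPR meta-learner.
#' @param shuffle_folds use shuffled folds instead of the default
#'   contiguous-in-time blocks (process data is serially correlated, so
#'   blocked folds are the safer default).
#' @param seed master seed.
#' @return a `stack_config`.
#' @export
stack_config <- function(base = model_config(), base_configs = NULL,
                         k_folds = 5, meta = c("gpr", "linear"),
                         gpr_max_points = 400, shuffle_folds = FALSE,
                         seed = 1) {
  meta <- match.arg(meta)
  stopifnot(k_folds >= 2)
  if (is.null(base_configs)) {
    mult <- c(0.75, 1, 1.25)
    base_configs <- lapply(1:3, function(i) {
      cfg <- base
      cfg$nodes_per_group <- max(1L, round(base$nodes_per_group * mult[i]))
      if (base$mode == "akbls") {
        cfg$m_fourier <- max(1L, round(base$m_fourier * mult[i]))
      }
      if (base$mode == "bls") {
        cfg$n_enhance <- max(1L, round(base$n_enhance * mult[i]))
      }
      cfg$sigma_scale <- base$sigma_scale * mult[i]
      cfg$seed <- derive_seed(seed, i)
      cfg
    })
  }
  structure(list(base_configs = base_configs, k_folds = k_folds,
                 meta = meta, gpr_max_points = gpr_max_points,
                 shuffle_folds = shuffle_folds, seed = seed),
            class = "stack_config")
}

# Contiguous (or seeded shuffled) fold assignment of n rows into k folds.
make_folds <- function(n, k, shuffle = FALSE, seed = 1) {
  fold <- sort(rep(seq_len(k), length.out = n))   # contiguous blocks 1..k
  if (shuffle) fold <- with_seed(seed, sample(fold))
  fold
}

#' Fit a stacking ensemble
#'
#' Builds the N x B meta-feature table from out-of-fold predictions (no
#' base model ever predicts a row it was trained on), fits the meta-learner
#' on it, then refits every base on the full training set.
#'
#' @param data a [process_dataset()] or list with `X` and `y`.
#' @param cfg a [stack_config()].
#' @return a `stack_model` retaining the meta-feature table and the fold
#'   bookkeeping for audit.
#' @export
fit_stacking <- function(data, cfg = stack_config()) {
  X <- as.matrix(data$X); y <- as.numeric(data$y)
  n <- nrow(X); k <- cfg$k_folds
  if (n < k) stop_bs("fewer samples than folds", "bs_bad_data")
  if (length(cfg$base_configs) != 3) {
    message(sprintf("stacking with %d base learners (default is 3)",
                    length(cfg$base_configs)))
  }
  fold <- make_folds(n, k, cfg$shuffle_folds, derive_seed(cfg$seed, 77))
  if (min(table(fold)) < 2) {
    stop_bs("a fold has fewer than 2 samples", "bs_bad_data")
  }
  B <- length(cfg$base_configs)
  meta <- matrix(NA_real_, n, B,
                 dimnames = list(NULL, paste0("base_", seq_len(B))))
  audit <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    audit[[f]] <- list(fold = f, train_rows = tr, test_rows = te)
    sub <- list(X = X[tr, , drop = FALSE], y = y[tr])
    for (b in seq_len(B)) {
      mb <- fit_model(sub, cfg$base_configs[[b]])
      meta[te, b] <- predict(mb, X[te, , drop = FALSE])
    }
  }
  meta_model <- NULL; meta_kind <- cfg$meta
  if (cfg$meta == "gpr") {
    meta_model <- tryCatch(
      fit_gpr(meta, y, max_points = cfg$gpr_max_points,
              seed = derive_seed(cfg$seed, 88)),
      error = function(e) NULL)
    if (is.null(meta_model)) {
      message("GPR meta-learner failed; falling back to linear meta-learner")
      meta_kind <- "linear"
    }
  }
  if (meta_kind == "linear") {
    D <- cbind(1, meta)
    meta_model <- list(coef = drop(chol_solve(
      crossprod(D) + diag(1e-8, ncol(D)), crossprod(D, y))))
    class(meta_model) <- "linear_meta"
  }
  bases <- lapply(cfg$base_configs, function(bc)
    fit_model(list(X = X, y = y), bc))
  structure(list(bases = bases, meta_model = meta_model,
                 meta_kind = meta_kind, meta_features = meta,
                 fold = fold, audit = audit, cfg = cfg,
                 variables = colnames(X)),
            class = "stack_model")
}

#' @export
print.stack_model <- function(x, ...) {
  cat(sprintf("<stack_model> %d base learners (%s), %s meta-learner\n",
              length(x$bases), x$bases[[1]]$mode, x$meta_kind))
  invisible(x)
}

#' Predict with a stacking ensemble
#'
#' @param object a `stack_model`.
#' @param newdata matrix, data frame or [process_dataset()].
#' @param ... ignored.
#' @return numeric prediction vector.
#' @export
predict.stack_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "process_dataset")) newdata$X else
    as.matrix(newdata)
  meta <- vapply(object$bases, function(b) predict(b, X),
                 numeric(nrow(X)))
  meta <- matrix(meta, nrow(X))
  if (object$meta_kind == "gpr") {
    predict(object$meta_model, meta)
  } else {
    drop(cbind(1, meta) %*% object$meta_model$coef)
  }
}
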