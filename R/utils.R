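# Internal helpers: seeded evaluation, assertions, linear solves.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG to a reproducible state, evaluates `expr`, and restores the
#' caller's RNG state so that no function in the package leaks hidden global
#' randomness.
#'
#' @param seed integer seed (must be finite, < 2^31).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a master seed; result stays in
# [0, 2^31 - 2] so it is always a valid R integer seed.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483647
}

stop_bs <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "broadsensor_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

check_finite_matrix <- function(x, name = deparse(substitute(x))) {
  if (!all(is.finite(x))) {
    stop_bs(sprintf("non-finite values in %s", name), "bs_nonfinite")
  }
  invisible(x)
}

# Solve (ridge + G) %*% X = B for symmetric positive definite (ridge*I + G),
# via Cholesky; falls back to a generic solve with a small added jitter if
# the factorization fails for numerical reasons.
chol_solve <- function(M, B) {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    jit <- 1e-10 * mean(diag(M))
    ch <- tryCatch(chol(M + diag(jit, nrow(M))), error = function(e) NULL)
  }
  if (is.null(ch)) {
    return(solve(M, B))
  }
  backsolve(ch, forwardsolve(t(ch), B))
}

# Minimum-norm least squares via SVD (pseudo-inverse), used as the gamma = 0
# fallback of the ridge output solver.
pinv_solve <- function(A, B, tol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > tol * max(sv$d)
  if (!any(keep)) {
    return(matrix(0, ncol(A), NCOL(B)))
  }
  sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% B) / sv$d[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
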