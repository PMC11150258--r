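# Evaluation metrics.

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((yhat - y)^2) / sum((y - mean(y))^2)`.
#'
#' @param y observed values (length >= 2, non-constant).
#' @param yhat predictions of the same length.
#' @return scalar R-squared (<= 1; can be negative for bad fits).
#' @export
r2_score <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) != length(yhat)) stop_bs("length mismatch", "bs_bad_data")
  if (length(y) < 2) stop_bs("need at least 2 observations", "bs_bad_data")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) {
    stop_bs("R-squared is undefined for a constant target", "bs_bad_data")
  }
  1 - sum((yhat - y)^2) / ss_tot
}

#' Root mean square error
#'
#' @param y observed values.
#' @param yhat predictions of the same length.
#' @return scalar RMSE (>= 0).
#' @export
rmse <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) != length(yhat)) stop_bs("length mismatch", "bs_bad_data")
  if (length(y) < 1) stop_bs("need at least 1 observation", "bs_bad_data")
  sqrt(mean((yhat - y)^2))
}

# RMSE on the standardized-target scale: errors divided by sd(y_reference).
# This is the scale on which ensemble results are reported by default, so
# that values are comparable across datasets with different target ranges.
rmse_std <- function(y, yhat, y_ref = y) {
  rmse(y, yhat) / max(stats::sd(y_ref), 1e-12)
}
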