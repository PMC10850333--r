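#' Root mean square error
#'
#' `sqrt(mean((y - yhat)^2))`, the RMSE reported for both calibration
#' (RMSE_C) and prediction (RMSE_P) sets. Targets are never transformed in
#' this package, so RMSE is always in impurity-mass-fraction units.
#'
#' @param y observed values.
#' @param yhat predicted values (same length).
#' @return Non-negative scalar.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop(sprintf("length mismatch: %d vs %d", length(y), length(yhat)))
  if (!length(y)) stop("empty input")
  sqrt(mean((y - yhat)^2))
}

#' Pearson correlation between truth and prediction
#'
#' The headline "R" statistic (R_C on the calibration set, R_P on the
#' prediction set). Pearson's product-moment correlation is used: the
#' ratio-of-sums formula printed in some reports evaluates to 0 at perfect
#' prediction and so cannot be the intended statistic (see
#' [printed_r_eq5()] for an audit implementation of that formula).
#'
#' @param y observed values (non-constant, length >= 2).
#' @param yhat predicted values.
#' @return Scalar in `[-1, 1]`.
#' @export
pearson_r <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop(sprintf("length mismatch: %d vs %d", length(y), length(yhat)))
  if (length(y) < 2L) stop("need at least 2 observations")
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0)
    stop("correlation undefined for constant input")
  stats::cor(y, yhat)
}

#' Audit evaluation of the printed correlation formula
#'
#' Evaluates `sqrt(sum((yhat - y)^2) / sum((yhat - mean(y))^2))` exactly as
#' the ratio formula is printed: the residual sum over the dispersion of
#' the predictions about the mean of the observed values. At perfect
#' prediction this is 0, not 1, which is why it is provided for audit only
#' and never used as the reported R.
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @return Non-negative scalar.
#' @export
printed_r_eq5 <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop(sprintf("length mismatch: %d vs %d", length(y), length(yhat)))
  den <- sum((yhat - mean(y))^2)
  if (den == 0) stop("zero denominator: predictions all equal mean(y)")
  sqrt(sum((yhat - y)^2) / den)
}

#' Evaluation report for a calibration/prediction split
#'
#' Computes Pearson R and RMSE on the calibration (training) and prediction
#' (test) sets, the four columns reported per model row: R_C, RMSE_C, R_P,
#' RMSE_P.
#'
#' @param y_cal,yhat_cal observed and predicted calibration values.
#' @param y_pred,yhat_pred observed and predicted test values.
#' @return Object of class `eval_report`: a list with `r_c`, `rmse_c`,
#'   `r_p`, `rmse_p`, and the sample counts.
#' @export
eval_report <- function(y_cal, yhat_cal, y_pred, yhat_pred) {
  structure(list(r_c = pearson_r(y_cal, yhat_cal),
                 rmse_c = rmse(y_cal, yhat_cal),
                 r_p = pearson_r(y_pred, yhat_pred),
                 rmse_p = rmse(y_pred, yhat_pred),
                 n_cal = length(y_cal), n_pred = length(y_pred)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("R_C=%.4f RMSE_C=%.4f | R_P=%.4f RMSE_P=%.4f (n=%d/%d)\n",
              x$r_c, x$rmse_c, x$r_p, x$rmse_p, x$n_cal, x$n_pred))
  invisible(x)
}
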