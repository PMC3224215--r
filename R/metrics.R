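# Prediction-quality measures for external test sets.

#' Coefficient of determination q-squared
#'
#' `q2 = 1 - sum((m - p)^2) / sum((m - mean(m))^2)`: one minus the
#' residual sum of squares over the total sum of squares about the mean of
#' the *measured* values. Equals 1 for perfect prediction, 0 for
#' predicting the measured mean, and can be arbitrarily negative when the
#' predictions are worse than the mean predictor — which happens in
#' particular when the training set's target range does not represent the
#' test set's.
#'
#' @param measured Numeric vector of measured values (length >= 2, not all
#'   identical).
#' @param predicted Numeric vector of predictions, same length.
#' @return The scalar q-squared.
#' @examples
#' q_squared(c(1, 2, 3), c(1, 2, 4)) # 0.5
#' @export
q_squared <- function(measured, predicted) {
  if (length(measured) != length(predicted)) {
    abort("measured and predicted must have the same length")
  }
  if (length(measured) < 2L) abort("need at least 2 observations")
  tss <- sum((measured - mean(measured))^2)
  if (tss == 0) {
    abort("q-squared is undefined when all measured values are identical")
  }
  1 - sum((measured - predicted)^2) / tss
}

#' Spearman rank correlation coefficient
#'
#' The Pearson correlation of mid-ranks (ties receive average ranks).
#' Invariant under strictly monotone transforms of either argument, so it
#' measures ranking quality even when predictions are miscalibrated in
#' scale or offset.
#'
#' @inheritParams q_squared
#' @return The scalar rank correlation in `[-1, 1]`.
#' @examples
#' spearman_rcc(1:4, c(1, 3, 2, 4)) # 0.8
#' @export
spearman_rcc <- function(measured, predicted) {
  if (length(measured) != length(predicted)) {
    abort("measured and predicted must have the same length")
  }
  if (length(measured) < 2L) abort("need at least 2 observations")
  rm_ <- rank(measured, ties.method = "average")
  rp_ <- rank(predicted, ties.method = "average")
  if (var(rm_) == 0 || var(rp_) == 0) {
    abort("rank correlation is undefined when one vector has no rank variance")
  }
  stats::cor(rm_, rp_)
}

#' Evaluate predictions against measured values
#'
#' Convenience wrapper computing both quality measures from a data frame
#' of paired values.
#'
#' @param data A data frame holding both columns.
#' @param measured,predicted Column names (strings) of the measured and
#'   predicted values; defaults `"pic50"` and `"predicted_pic50"`.
#' @return A one-row tibble with columns `q2`, `srcc`, `n`.
#' @examples
#' evaluate_predictions(
#'   tibble::tibble(pic50 = c(1, 2, 3), predicted_pic50 = c(1, 2, 4))
#' )
#' @export
evaluate_predictions <- function(data, measured = "pic50",
                                 predicted = "predicted_pic50") {
  stopifnot(is.data.frame(data), measured %in% names(data),
            predicted %in% names(data))
  m <- data[[measured]]
  p <- data[[predicted]]
  tibble::tibble(
    q2 = q_squared(m, p),
    srcc = spearman_rcc(m, p),
    n = length(m)
  )
}
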