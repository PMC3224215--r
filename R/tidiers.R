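# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' Tidy a two-step model
#'
#' One row per feature kept by the normalizer, with stage-1 weight,
#' selection status and (for selected features) the stage-2 weight.
#'
#' @param x A `two_step_model`.
#' @param ... Unused.
#' @return A tibble with columns `feature`, `block`, `position`,
#'   `component`, `stage1_weight`, `selected`, `stage2_weight`.
#' @export
tidy.two_step_model <- function(x, ...) {
  out <- tibble::tibble(
    feature = x$normalizer$kept_names,
    stage1_weight = x$stage1$w,
    selected = seq_along(x$stage1$w) %in% x$selected,
    stage2_weight = NA_real_
  )
  out$stage2_weight[x$selected] <- x$stage2$w
  info <- feature_info_from_names(out$feature)
  dplyr::bind_cols(
    info[, c("feature", "block", "position", "component")],
    out[, c("stage1_weight", "selected", "stage2_weight")]
  )
}

#' One-row summary of a two-step model
#'
#' @param x A `two_step_model`.
#' @param ... Unused.
#' @return A one-row tibble: sample size, peptide length, feature counts
#'   at each stage, chosen regularization strengths, threshold and seed.
#' @export
glance.two_step_model <- function(x, ...) {
  p <- x$provenance
  tibble::tibble(
    n_train = p$n_train,
    peptide_length = x$peptide_length,
    d_initial = p$d_initial,
    d_kept = p$d_kept,
    d_selected = p$d_selected,
    lambda1 = x$lambda1,
    lambda2 = x$lambda2,
    threshold = x$threshold,
    seed = p$seed
  )
}

#' Tidy a cross-validation result
#'
#' @param x A `cv_result` from [cross_validate_lambda()].
#' @param ... Unused.
#' @return A tibble with one row per candidate: `lambda`, `mean_error`,
#'   `chosen`.
#' @export
tidy.cv_result <- function(x, ...) {
  dplyr::mutate(x$summary, chosen = .data$lambda == x$chosen_lambda)
}

#' One-row summary of a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return A one-row tibble: stage, chosen lambda, its mean validation
#'   error, repeats, folds and seed.
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    stage = x$stage,
    chosen_lambda = x$chosen_lambda,
    min_mean_error = min(x$summary$mean_error),
    k_repeats = x$k_repeats,
    n_folds = x$n_folds,
    seed = x$seed
  )
}

#' Plot a cross-validation curve
#'
#' Mean validation error per candidate (line and points) over the
#' per-fold errors (faint), with the chosen lambda highlighted. The
#' lambda axis is logarithmic.
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$per_fold, ggplot2::aes(x = .data$lambda, y = .data$error)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.8) +
    ggplot2::geom_line(
      data = object$summary,
      ggplot2::aes(y = .data$mean_error),
      color = "steelblue"
    ) +
    ggplot2::geom_point(
      data = object$summary,
      ggplot2::aes(y = .data$mean_error),
      color = "steelblue", size = 2
    ) +
    ggplot2::geom_vline(
      xintercept = object$chosen_lambda,
      linetype = "dashed", color = "firebrick"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = sprintf("lambda%d (log scale)", object$stage),
      y = "validation error",
      title = sprintf(
        "%d x %d-fold CV, stage %d: chosen lambda = %g",
        object$k_repeats, object$n_folds, object$stage,
        object$chosen_lambda
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot the weight profile of a two-step model
#'
#' Stage-1 absolute weights across the feature space on a log scale,
#' colored by encoder block, with the selection threshold as a horizontal
#' line; selected features are emphasized.
#'
#' @param object A `two_step_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.two_step_model <- function(object, ...) {
  td <- tidy(object)
  td$index <- seq_len(nrow(td))
  ggplot2::ggplot(
    td,
    ggplot2::aes(
      x = .data$index, y = pmax(abs(.data$stage1_weight), 1e-12),
      color = .data$block, alpha = .data$selected
    )
  ) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::geom_hline(
      yintercept = object$threshold,
      linetype = "dashed", color = "grey30"
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.25, `TRUE` = 1)) +
    ggplot2::labs(
      x = "feature index (kept columns)",
      y = "|stage-1 weight| (log scale)",
      title = sprintf(
        "%d of %d features selected at threshold %g",
        length(object$selected), length(object$stage1$w), object$threshold
      )
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plot of predicted versus measured values
#'
#' @param data A data frame holding both columns.
#' @param measured,predicted Column names; defaults `"pic50"` and
#'   `"predicted_pic50"`.
#' @return A ggplot object with the identity line and both quality
#'   measures in the subtitle.
#' @export
plot_prediction_scatter <- function(data, measured = "pic50",
                                    predicted = "predicted_pic50") {
  ev <- evaluate_predictions(data, measured, predicted)
  ggplot2::ggplot(
    data,
    ggplot2::aes(x = .data[[measured]], y = .data[[predicted]])
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey60") +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::labs(
      x = "measured pIC50", y = "predicted pIC50",
      subtitle = sprintf("q2 = %.3f, SRCC = %.3f (n = %d)", ev$q2, ev$srcc, ev$n)
    ) +
    ggplot2::theme_minimal()
}
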