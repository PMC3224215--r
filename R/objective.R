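# The regularized training objective:
#
#   L(w, b) = (1 - lambda1 - lambda2)/N * sum_i mu_i g(f(x_i), m_i)
#             + lambda1 * sum_j |w_j| + lambda2 * sum_j w_j^2
#
# with f(x) = w'x + b and g either the robust logarithmic loss
# log(1 + (f - m)^2) or the squared loss (f - m)^2. The bias is never
# penalized.

#' Linear scoring model
#'
#' A hyperplane scoring function `f(x) = w'x + b`: `w` is the hyperplane
#' normal, `b` the offset. Predicted pIC50 values are the (scaled) distances
#' of feature vectors to this hyperplane.
#'
#' @param w Numeric weight vector (finite).
#' @param b Numeric bias scalar (finite).
#' @return A `linear_model` object.
#' @examples
#' score_linear(linear_model(c(1, 2), 0), c(3, 4)) # 11
#' @export
linear_model <- function(w, b = 0) {
  w <- as.double(w)
  b <- as.double(b)
  if (!all(is.finite(w)) || length(b) != 1L || !is.finite(b)) {
    abort("linear model needs finite weights and a finite scalar bias")
  }
  structure(list(w = w, b = b), class = "linear_model")
}

#' @export
print.linear_model <- function(x, ...) {
  nz <- sum(abs(x$w) >= 1e-8)
  cat(sprintf(
    "<linear_model> d = %d (%d weights above 1e-8), b = %.4g\n",
    length(x$w), nz, x$b
  ))
  invisible(x)
}

#' Evaluate the linear scoring function
#'
#' @param model A [linear_model()].
#' @param x A numeric vector of length `d`, or an `n x d` matrix for many
#'   peptides at once.
#' @return A numeric scalar (vector input) or a vector of `n` scores.
#' @export
score_linear <- function(model, x) {
  stopifnot(inherits(model, "linear_model"))
  if (is.matrix(x)) {
    if (ncol(x) != length(model$w)) {
      abort(sprintf(
        "feature matrix has %d columns, model has %d weights",
        ncol(x), length(model$w)
      ))
    }
    return(drop(x %*% model$w) + model$b)
  }
  if (length(x) != length(model$w)) {
    abort(sprintf(
      "feature vector has length %d, model has %d weights",
      length(x), length(model$w)
    ))
  }
  sum(model$w * x) + model$b
}

#' Robust logarithmic loss
#'
#' `g(f, m) = log(1 + (f - m)^2)` (natural logarithm). The loss grows very
#' slowly with large deviations, so single outliers influence the fit far
#' less than under the squared loss; it is bounded above by the squared
#' residual everywhere.
#'
#' @param f Predicted score(s).
#' @param m Measured target(s); recycled against `f`.
#' @return Non-negative loss value(s), 0 exactly when `f == m`.
#' @examples
#' soft_loss(2, 1) # log(2)
#' @export
soft_loss <- function(f, m) {
  log1p((f - m)^2)
}

#' Derivative of the loss with respect to the prediction
#'
#' `2 (f - m) / (1 + (f - m)^2)` for the soft loss, `2 (f - m)` for the
#' squared loss.
#'
#' @inheritParams soft_loss
#' @param loss `"soft"` (default) or `"squared"`.
#' @return The derivative dg/df, vectorized.
#' @export
loss_gradient <- function(f, m, loss = c("soft", "squared")) {
  loss <- match.arg(loss)
  r <- f - m
  if (loss == "soft") 2 * r / (1 + r^2) else 2 * r
}

#' Regularization penalty of a weight vector
#'
#' By default the p-th power of the p-norm: `sum(|w|)` for `p = 1` (Lasso)
#' and `sum(w^2)` for `p = 2` (ridge) — the standard forms, which keep the
#' L2 gradient linear. `form = "norm"` gives the literal p-norm
#' `(sum |w|^p)^(1/p)` instead. The bias is never part of the penalty.
#'
#' @param w Numeric weight vector.
#' @param p Penalty order, 1 or 2.
#' @param form `"power"` (default) or `"norm"`.
#' @return A non-negative scalar.
#' @examples
#' penalty(c(1, -2, 3), p = 1) # 6
#' penalty(c(1, -2, 3), p = 2) # 14
#' @export
penalty <- function(w, p, form = c("power", "norm")) {
  form <- match.arg(form)
  if (!p %in% c(1, 2)) abort("penalty order p must be 1 or 2")
  s <- sum(abs(w)^p)
  if (form == "norm") s^(1 / p) else s
}

#' Objective configuration
#'
#' Collects the regularization strengths, loss choice and optional
#' per-sample weights of the training objective. The data-term prefactor is
#' `(1 - lambda1 - lambda2)/N`, so `lambda1 + lambda2` must stay below 1.
#' The two-step pipeline only ever sets one lambda at a time (L1 in stage
#' 1, L2 in stage 2), but both may be nonzero here.
#'
#' @param lambda1 L1 (Lasso) strength in `[0, 1)`.
#' @param lambda2 L2 (ridge) strength in `[0, 1)`.
#' @param loss `"soft"` (robust logarithmic, the default) or `"squared"`.
#' @param sample_weights Optional positive per-sample weights `mu_i`
#'   (default: all 1). Recycled checks happen at evaluation time.
#' @param penalty_form `"power"` (default) or `"norm"`, see [penalty()].
#' @return An `objective_config` object.
#' @export
objective_config <- function(lambda1 = 0, lambda2 = 0,
                             loss = c("soft", "squared"),
                             sample_weights = NULL,
                             penalty_form = c("power", "norm")) {
  loss <- match.arg(loss)
  penalty_form <- match.arg(penalty_form)
  if (lambda1 < 0 || lambda1 >= 1 || lambda2 < 0 || lambda2 >= 1) {
    abort("lambda1 and lambda2 must each lie in [0, 1)")
  }
  if (lambda1 + lambda2 >= 1) {
    abort("lambda1 + lambda2 must be below 1 (data-term prefactor positive)")
  }
  if (!is.null(sample_weights) && any(sample_weights <= 0)) {
    abort("sample_weights must be strictly positive")
  }
  structure(
    list(
      lambda1 = lambda1, lambda2 = lambda2, loss = loss,
      sample_weights = sample_weights, penalty_form = penalty_form
    ),
    class = "objective_config"
  )
}

check_objective_shapes <- function(model, X, targets, cfg) {
  if (ncol(X) != length(model$w)) {
    abort(sprintf(
      "feature matrix has %d columns, model has %d weights",
      ncol(X), length(model$w)
    ))
  }
  if (nrow(X) != length(targets)) {
    abort(sprintf(
      "feature matrix has %d rows, targets has length %d",
      nrow(X), length(targets)
    ))
  }
  mu <- cfg$sample_weights %||% rep(1, nrow(X))
  if (length(mu) != nrow(X)) {
    abort("sample_weights length must match the number of samples")
  }
  mu
}

#' Value of the regularized objective
#'
#' `(1 - lambda1 - lambda2)/N * sum_i mu_i g(f(x_i), m_i)
#'  + lambda1 * penalty(w, 1) + lambda2 * penalty(w, 2)`.
#'
#' @param model A [linear_model()].
#' @param X Numeric `n x d` feature matrix.
#' @param targets Numeric vector of `n` measured values.
#' @param cfg An [objective_config()].
#' @return The scalar objective value.
#' @export
objective_value <- function(model, X, targets, cfg = objective_config()) {
  X <- as.matrix(X)
  mu <- check_objective_shapes(model, X, targets, cfg)
  f <- score_linear(model, X)
  g <- if (cfg$loss == "soft") soft_loss(f, targets) else (f - targets)^2
  pref <- (1 - cfg$lambda1 - cfg$lambda2) / nrow(X)
  pref * sum(mu * g) +
    cfg$lambda1 * penalty(model$w, 1, cfg$penalty_form) +
    cfg$lambda2 * penalty(model$w, 2, cfg$penalty_form)
}

#' Gradient of the regularized objective
#'
#' Analytic gradient with respect to `(w, b)`. The L1 term contributes
#' `lambda1 * sign(w_i)` with the zero subgradient `sign(0) = 0` (the L1
#' derivative is undefined at vanishing weights; the zero choice lets a
#' weight leave zero only when the data gradient pushes it). The bias
#' receives only the data-term gradient.
#'
#' @inheritParams objective_value
#' @return A list with components `w` (length-`d` vector) and `b` (scalar).
#' @export
objective_gradient <- function(model, X, targets, cfg = objective_config()) {
  X <- as.matrix(X)
  mu <- check_objective_shapes(model, X, targets, cfg)
  f <- score_linear(model, X)
  pref <- (1 - cfg$lambda1 - cfg$lambda2) / nrow(X)
  u <- pref * mu * loss_gradient(f, targets, cfg$loss)
  gw <- drop(crossprod(X, u))
  if (cfg$penalty_form == "power") {
    gw <- gw + cfg$lambda1 * sign(model$w) + 2 * cfg$lambda2 * model$w
  } else {
    # literal p-norm variant: d/dw (sum|w|) = sign(w); d/dw sqrt(sum w^2) = w/||w||
    n2 <- sqrt(sum(model$w^2))
    gw <- gw + cfg$lambda1 * sign(model$w) +
      if (n2 > 0) cfg$lambda2 * model$w / n2 else 0
  }
  list(w = gw, b = sum(u))
}
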