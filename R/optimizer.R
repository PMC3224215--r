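# Rprop minimization of the regularized objective, plus the exact
# closed-form ridge solver used as the package's primary correctness
# oracle for the squared-loss + L2 case.

#' Rprop optimizer settings
#'
#' The resilient-propagation (Rprop) optimizer adapts one step size per
#' parameter from the sign pattern of successive partial derivatives, so
#' it is insensitive to gradient magnitude — which is what makes it usable
#' with the kinked L1 term. This package implements the iRprop- variant
#' (no weight backtracking) with the standard growth/shrink constants.
#'
#' @param eta_plus Step growth factor on consistent derivative sign
#'   (default 1.2).
#' @param eta_minus Step shrink factor on a sign flip (default 0.5).
#' @param delta0 Initial per-parameter step (default 0.1).
#' @param delta_min Smallest step (default `1e-9`, one decade below the
#'   `1e-8` feature-selection threshold so weights can settle below the
#'   cut).
#' @param delta_max Largest step (default 50).
#' @param max_iter Iteration cap (default 30000). Under an L1 penalty the
#'   irrelevant weights reach the sub-threshold band only by annealing
#'   their sign-flip steps, which at small `lambda1` takes tens of
#'   thousands of the cheap Rprop iterations; the cap is sized so the
#'   selection threshold acts on the annealed solution. Converged fits
#'   stop far earlier via `tol`.
#' @param tol Stop when the objective changes by less than this over a
#'   moving iteration whose steps have annealed to the `delta_min` scale
#'   (default `1e-10`).
#' @return An `rprop_config` object.
#' @export
rprop_config <- function(eta_plus = 1.2, eta_minus = 0.5, delta0 = 0.1,
                         delta_min = 1e-9, delta_max = 50,
                         max_iter = 30000L, tol = 1e-10) {
  stopifnot(
    eta_plus > 1, eta_minus > 0, eta_minus < 1,
    delta_min > 0, delta_min < delta0, delta0 < delta_max,
    max_iter >= 1
  )
  structure(
    list(
      eta_plus = eta_plus, eta_minus = eta_minus, delta0 = delta0,
      delta_min = delta_min, delta_max = delta_max,
      max_iter = as.integer(max_iter), tol = tol
    ),
    class = "rprop_config"
  )
}

#' Minimize the regularized objective with Rprop
#'
#' Runs iRprop-: every parameter (each weight and the bias) keeps a
#' private step size that grows by `eta_plus` while its partial derivative
#' keeps its sign and shrinks by `eta_minus` when the sign flips, in which
#' case the stored derivative is zeroed so the parameter sits out one
#' iteration. Parameters move by `-sign(gradient) * step`. The returned
#' model is the best-objective iterate seen (including the start), which
#' guards against terminal oscillation. With an L1 penalty weights are not
#' set exactly to zero, but irrelevant ones oscillate into the
#' `delta_min`-sized neighbourhood of zero, well below the `1e-8`
#' selection threshold.
#'
#' @param X Numeric `n x d` feature matrix (normalized features).
#' @param targets Numeric vector of `n` measured values.
#' @param cfg An [objective_config()]; only the default `"power"` penalty
#'   form is supported by the optimizer.
#' @param opt An [rprop_config()].
#' @param init Optional starting [linear_model()]; the default starts at
#'   `w = 0`, `b = mean(targets)`, which is deterministic and on the scale
#'   of the data.
#' @return An `rprop_fit` list: `model` ([linear_model()]),
#'   `n_iterations`, `final_objective`, `converged`.
#' @examples
#' X <- matrix(c(1, 2), ncol = 1)
#' fit <- rprop_minimize(X, c(2, 4), objective_config(loss = "squared"))
#' round(fit$model$w, 4) # close to 2
#' @export
rprop_minimize <- function(X, targets, cfg = objective_config(),
                           opt = rprop_config(), init = NULL) {
  X <- as.matrix(X)
  stopifnot(inherits(cfg, "objective_config"), inherits(opt, "rprop_config"))
  if (cfg$penalty_form != "power") {
    abort("rprop_minimize supports only the default 'power' penalty form")
  }
  if (is.null(init)) {
    init <- linear_model(rep(0, ncol(X)), mean(targets))
  }
  mu <- check_objective_shapes(init, X, targets, cfg)
  res <- rprop_core(
    X, as.double(targets), cfg$lambda1, cfg$lambda2, as.double(mu),
    cfg$loss == "soft", init$w, init$b,
    opt$eta_plus, opt$eta_minus, opt$delta0, opt$delta_min, opt$delta_max,
    opt$max_iter, opt$tol
  )
  structure(
    list(
      model = linear_model(drop(res$w), res$b),
      n_iterations = res$n_iterations,
      final_objective = res$final_objective,
      converged = res$converged
    ),
    class = "rprop_fit"
  )
}

#' @export
print.rprop_fit <- function(x, ...) {
  cat(sprintf(
    "<rprop_fit> %d iterations (%s), objective %.6g\n",
    x$n_iterations, if (x$converged) "converged" else "iteration cap",
    x$final_objective
  ))
  invisible(x)
}

#' Closed-form ridge solution (squared loss + L2)
#'
#' For the squared loss with an L2 penalty the objective is quadratic and
#' its exact minimizer solves a symmetric positive-definite linear system,
#' handled here by Cholesky factorization of the centered normal
#' equations. The bias is unpenalized and absorbs the target mean. Under
#' the default convention the data term is scaled by `(1 - lambda2)/N` as
#' in the full objective; `prefactor = "plain"` uses `1/N` instead.
#'
#' This solver is the package's primary correctness oracle: Rprop run on
#' the same quadratic problem must land on the same minimizer.
#'
#' @param X Numeric `n x d` feature matrix.
#' @param targets Numeric vector of `n` measured values.
#' @param lambda2 L2 strength, `>= 0` (and `< 1` under the default
#'   convention).
#' @param prefactor `"one-minus-lambda"` (default) or `"plain"`.
#' @return The exact minimizer as a [linear_model()].
#' @export
ridge_closed_form <- function(X, targets, lambda2,
                              prefactor = c("one-minus-lambda", "plain")) {
  prefactor <- match.arg(prefactor)
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(lambda2 >= 0, n >= 1, length(targets) == n)
  a <- if (prefactor == "one-minus-lambda") {
    if (lambda2 >= 1) abort("lambda2 must be < 1 under the default convention")
    (1 - lambda2) / n
  } else {
    1 / n
  }
  xm <- colMeans(X)
  ym <- mean(targets)
  Xc <- sweep(X, 2L, xm)
  yc <- targets - ym
  # stationarity: a * Xc'Xc w + lambda2 w = a * Xc'yc
  A <- crossprod(Xc)
  diag(A) <- diag(A) + lambda2 / a
  R <- tryCatch(chol(A), error = function(e) {
    abort(paste0(
      "normal equations are singular (collinear features with lambda2 = 0); ",
      "use lambda2 > 0"
    ))
  })
  w <- backsolve(R, backsolve(R, crossprod(Xc, yc), transpose = TRUE))
  w <- drop(w)
  linear_model(w, ym - sum(xm * w))
}
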