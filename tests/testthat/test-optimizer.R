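# Rprop minimization and the closed-form ridge oracle.

test_that("Rprop finds the unique minimum of a tiny quadratic problem", {
  X <- matrix(c(1, 2), 2, 1)
  fit <- rprop_minimize(
    X, c(5, 10), objective_config(loss = "squared"),
    rprop_config(tol = 1e-16, max_iter = 5000)
  )
  expect_lt(abs(fit$model$w - 5), 1e-6)
  expect_lt(abs(fit$model$b), 1e-5)
  expect_true(fit$converged)
})

test_that("Rprop with squared loss + L2 agrees with the ridge oracle", {
  set.seed(21)
  X <- matrix(rnorm(20 * 10), 20, 10)
  y <- drop(X %*% rnorm(10)) + rnorm(20, sd = 0.3)
  cf <- ridge_closed_form(X, y, 0.2)
  fit <- rprop_minimize(X, y, objective_config(lambda2 = 0.2, loss = "squared"))
  expect_lt(max(abs(fit$model$w - cf$w)), 1e-4)
  expect_lt(abs(fit$model$b - cf$b), 1e-4)
})

test_that("Rprop tracks the best-seen objective and never reports worse than init", {
  set.seed(22)
  X <- matrix(rnorm(15 * 8), 15, 8)
  y <- rnorm(15)
  cfg <- objective_config(lambda1 = 0.1)
  init <- linear_model(rnorm(8), 0)
  fit <- rprop_minimize(X, y, cfg, init = init)
  expect_lte(fit$final_objective, objective_value(init, X, y, cfg))
  # the reported objective is the objective of the returned model
  expect_equal(
    fit$final_objective,
    objective_value(fit$model, X, y, cfg),
    tolerance = 1e-12
  )
  # deterministic: same data, same init, same result
  fit2 <- rprop_minimize(X, y, cfg, init = init)
  expect_identical(fit$model$w, fit2$model$w)
  expect_identical(fit$model$b, fit2$model$b)
})

test_that("L1 Rprop drives irrelevant weights below the selection threshold", {
  prob <- gaussian_lasso_problem(seed = 23)
  cfg <- objective_config(lambda1 = 0.1, loss = "soft")
  fit <- rprop_minimize(prob$X, prob$y, cfg)
  sel <- select_features(fit$model)
  expect_true(all(prob$support %in% sel))
  off <- setdiff(seq_along(fit$model$w), sel)
  expect_true(all(abs(fit$model$w[off]) < 1e-8))

  # squared-loss analogue: support agrees with coordinate-descent Lasso
  cfg_sq <- objective_config(lambda1 = 0.1, loss = "squared")
  fit_sq <- rprop_minimize(prob$X, prob$y, cfg_sq)
  gl <- glmnet::glmnet(
    prob$X, prob$y,
    lambda = 0.1 / (2 * (1 - 0.1)),
    standardize = FALSE, thresh = 1e-12
  )
  gl_support <- which(abs(as.numeric(gl$beta)) > 1e-8)
  expect_identical(select_features(fit_sq$model), gl_support)
})

test_that("sparsity is non-decreasing in lambda1 on a fixed problem", {
  prob <- gaussian_lasso_problem(seed = 24, n = 40, d = 80)
  n_below <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.3), function(l1) {
    fit <- rprop_minimize(prob$X, prob$y, objective_config(lambda1 = l1))
    sum(abs(fit$model$w) < 1e-8)
  }, numeric(1L))
  expect_true(all(diff(n_below) >= 0))
})

test_that("closed-form ridge solves the exact-fit and penalty-dominated limits", {
  # exact fit, lambda2 = 0
  cf <- ridge_closed_form(matrix(c(1, 2), 2, 1), c(2, 4), 0)
  expect_equal(drop(cf$w), 2, tolerance = 1e-12)
  expect_equal(cf$b, 0, tolerance = 1e-12)

  # penalty-dominated: w -> 0 and the unpenalized bias absorbs the mean
  set.seed(25)
  X <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10, mean = 4)
  cf2 <- ridge_closed_form(X, y, 0.9999)
  expect_lt(max(abs(cf2$w)), 1e-3)
  expect_equal(cf2$b, mean(y), tolerance = 1e-2)

  # collinear features with lambda2 = 0 raise an actionable error
  Xc <- cbind(X, X[, 1L])
  expect_error(ridge_closed_form(Xc, y, 0), "lambda2 > 0")
})

test_that("the ridge solution is a stationary point of the objective", {
  set.seed(26)
  X <- matrix(rnorm(30 * 5), 30, 5)
  y <- drop(X %*% rnorm(5)) + rnorm(30)
  cf <- ridge_closed_form(X, y, 0.3)
  g <- objective_gradient(
    cf, X, y, objective_config(lambda2 = 0.3, loss = "squared")
  )
  expect_lt(max(abs(c(g$w, g$b))), 1e-8)
})
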