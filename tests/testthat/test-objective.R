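# The regularized objective, its loss functions, penalties and gradient.

test_that("linear scoring returns w'x + b", {
  expect_equal(score_linear(linear_model(c(0, 0), 3), c(5, 7)), 3)
  expect_equal(score_linear(linear_model(c(1, 2), 0), c(3, 4)), 11)
  expect_equal(score_linear(linear_model(c(1, -1), 0.5), c(2, 2)), 0.5)
  # matrix form scores rows
  X <- rbind(c(3, 4), c(1, 0))
  expect_equal(score_linear(linear_model(c(1, 2), 1), X), c(12, 2))
  expect_error(score_linear(linear_model(c(1, 2)), c(1, 2, 3)), "length")
})

test_that("soft loss matches its closed form and is dominated by squared loss", {
  expect_equal(soft_loss(2, 2), 0)
  expect_equal(soft_loss(3, 2), log(2))
  expect_equal(soft_loss(5, 2), log(10))
  # robustness: log(1 + r^2) <= r^2 everywhere
  r <- seq(-10, 10, by = 0.37)
  expect_true(all(soft_loss(r, 0) <= r^2))
})

test_that("loss gradient is the analytic derivative", {
  expect_equal(loss_gradient(2, 2), 0)
  expect_equal(loss_gradient(3, 2), 1) # 2r/(1+r^2) at r = 1
  expect_equal(loss_gradient(3, 2, loss = "squared"), 2)
  # finite-difference oracle at assorted points
  for (r0 in c(-3.2, -0.7, 0.4, 2.9)) {
    num <- fd_grad(function(f) soft_loss(f, 1.5), 1.5 + r0)
    expect_equal(loss_gradient(1.5 + r0, 1.5), num, tolerance = 1e-6)
  }
})

test_that("penalties use the p-th power by default, the literal norm on request", {
  w <- c(1, -2, 3)
  expect_equal(penalty(w, 1), 6)
  expect_equal(penalty(w, 2), 14)
  expect_equal(penalty(numeric(3), 1), 0)
  expect_equal(penalty(numeric(3), 2), 0)
  expect_equal(penalty(w, 2, form = "norm"), sqrt(14))
  expect_error(penalty(w, 3), "1 or 2")
})

test_that("objective value composes data term and penalties correctly", {
  X <- rbind(1, 2)
  m <- c(1, 2)
  # perfect fit: only the L1 penalty remains
  expect_equal(
    objective_value(linear_model(1, 0), X, m, objective_config(lambda1 = 0.1)),
    0.1
  )
  # no penalties: plain mean loss
  cfg0 <- objective_config()
  expect_equal(
    objective_value(linear_model(0, 0), X, m, cfg0),
    mean(soft_loss(0, m))
  )
  # zero model on zero targets is 0 for any lambdas
  expect_equal(
    objective_value(
      linear_model(0, 0), X, c(0, 0),
      objective_config(lambda1 = 0.3, lambda2 = 0.2)
    ),
    0
  )
  expect_error(
    objective_value(linear_model(c(1, 2)), X, m, cfg0),
    "columns"
  )
})

test_that("objective gradient matches central finite differences", {
  set.seed(11)
  X <- matrix(rnorm(8 * 5), 8, 5)
  m <- rnorm(8)
  cfg <- objective_config(lambda1 = 0.1, lambda2 = 0.05, loss = "soft")
  for (rep in 1:3) {
    w <- runif(5, min = 0.05, max = 1) * sample(c(-1, 1), 5, replace = TRUE)
    b <- rnorm(1)
    g <- objective_gradient(linear_model(w, b), X, m, cfg)
    num <- fd_grad(
      function(th) {
        objective_value(linear_model(th[1:5], th[6]), X, m, cfg)
      },
      c(w, b)
    )
    expect_equal(c(g$w, g$b), num, tolerance = 1e-5)
  }
})

test_that("gradient special cases: zero point, L2 term, sign(0) subgradient", {
  X <- matrix(c(1, -1, 2, 0), 2, 2)
  g0 <- objective_gradient(
    linear_model(c(0, 0), 0), X, c(0, 0), objective_config()
  )
  expect_equal(g0$w, c(0, 0))
  expect_equal(g0$b, 0)

  # lambda2-only quadratic contribution is 2 * lambda2 * w
  w <- c(0.4, -1.2)
  cfg2 <- objective_config(lambda2 = 0.3)
  cfg0 <- objective_config()
  m <- c(1, -1)
  mdl <- linear_model(w, 0)
  d <- objective_gradient(mdl, X, m, cfg2)$w -
    (1 - 0.3) / (1 - 0) * objective_gradient(mdl, X, m, cfg0)$w
  expect_equal(d, 2 * 0.3 * w)

  # at w = 0 the L1 term contributes nothing (zero subgradient)
  cfg1 <- objective_config(lambda1 = 0.5)
  g <- objective_gradient(linear_model(c(0, 0), 0), X, c(0, 0), cfg1)
  expect_equal(g$w, c(0, 0))
})

test_that("scaling all sample weights scales the data term only", {
  set.seed(12)
  X <- matrix(rnorm(12), 4, 3)
  m <- rnorm(4)
  w <- rnorm(3)
  mdl <- linear_model(w, 0.2)
  base <- objective_config(lambda1 = 0.1, sample_weights = rep(1, 4))
  scaled <- objective_config(lambda1 = 0.1, sample_weights = rep(3, 4))
  pen <- 0.1 * penalty(w, 1)
  expect_equal(
    objective_value(mdl, X, m, scaled) - pen,
    3 * (objective_value(mdl, X, m, base) - pen)
  )
})
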