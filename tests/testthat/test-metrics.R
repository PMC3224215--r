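# q-squared and Spearman rank correlation.

test_that("q-squared identities and worked example", {
  m <- c(4.2, 5.1, 6.3, 7.0)
  expect_equal(q_squared(m, m), 1)
  expect_equal(q_squared(m, rep(mean(m), 4)), 0)
  expect_equal(q_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  # worse than the mean predictor goes negative
  expect_lt(q_squared(c(1, 2, 3), c(30, -10, 5)), 0)
  expect_error(q_squared(c(2, 2, 2), c(1, 2, 3)), "identical")
  expect_error(q_squared(1:3, 1:4), "length")
})

test_that("q-squared matches a brute-force evaluation on random vectors", {
  set.seed(41)
  for (i in 1:10) {
    m <- rnorm(20, mean = 6)
    p <- m + rnorm(20, sd = runif(1, 0, 3))
    brute <- 1 - sum((m - p)^2) / sum((m - mean(m))^2)
    expect_equal(q_squared(m, p), brute, tolerance = 1e-12)
  }
})

test_that("Spearman rank correlation uses mid-ranks and detects order", {
  m <- c(1.2, 3.4, 2.2, 8.0)
  # any strictly increasing transform of m correlates perfectly
  expect_equal(spearman_rcc(m, exp(m)), 1)
  expect_equal(spearman_rcc(m, rank(m)), 1)
  expect_equal(spearman_rcc(m, -m), -1)
  expect_equal(spearman_rcc(1:4, c(1, 3, 2, 4)), 0.8)
  # ties handled by mid-ranks: agrees with the base-R implementation
  set.seed(42)
  a <- sample(1:5, 30, replace = TRUE)
  b <- a + sample(0:2, 30, replace = TRUE)
  expect_equal(
    spearman_rcc(a, b),
    stats::cor(a, b, method = "spearman")
  )
  expect_error(spearman_rcc(c(1, 1, 1), 1:3), "rank variance")
})

test_that("SRCC is invariant under strictly monotone transforms", {
  set.seed(43)
  m <- rnorm(25)
  p <- m + rnorm(25)
  r0 <- spearman_rcc(m, p)
  expect_equal(spearman_rcc(exp(m), p), r0)
  expect_equal(spearman_rcc(m, 3 * p - 100), r0)
  expect_equal(spearman_rcc(m, atan(p)), r0)
})

test_that("evaluate_predictions reports both measures from a data frame", {
  ev <- evaluate_predictions(
    tibble::tibble(pic50 = c(1, 2, 3), predicted_pic50 = c(1, 2, 4))
  )
  expect_equal(ev$q2, 0.5)
  expect_equal(ev$n, 3L)
  expect_equal(ev$srcc, 1)
})
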