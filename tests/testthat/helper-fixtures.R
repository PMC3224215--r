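# Shared fixture builders. Everything is generated in code at test time.

# small peptide training set with planted signal; cheap enough for unit tests
tiny_sim <- function(seed = 1, n = 40, length = 6, n_properties = 4,
                     support_size = 3, noise_sd = 0.1, n_test = 0,
                     test_target_shift = 0) {
  simulate_regression_dataset(
    n = n, length = length,
    descriptors = simulate_descriptor_table(n_properties, seed = seed + 500L),
    support_size = support_size, effect_size = 1, noise_sd = noise_sd,
    seed = seed, n_test = n_test, test_target_shift = test_target_shift
  )
}

# quick run_config for unit tests (coarser CV than the default protocol)
tiny_config <- function(seed = 1, ...) {
  run_config(
    lambda1_grid = c(0.01, 0.05, 0.1),
    lambda2_grid = c(0.001, 0.01, 0.1),
    k_repeats = 2, n_folds = 5, seed = seed, ...
  )
}

# standardized Gaussian design with a planted sparse linear signal
# (no peptide structure; used where exact support identification matters)
gaussian_lasso_problem <- function(seed, n = 50, d = 200, support_size = 5,
                                   noise_sd = 0.1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * d), n, d)
    X <- scale(X) * sqrt(n / (n - 1)) # population standardization
    support <- sort(sample.int(d, support_size))
    w <- numeric(d)
    w[support] <- sample(c(-1, 1), support_size, replace = TRUE)
    y <- drop(X %*% w) + rnorm(n, sd = noise_sd)
    list(X = X, y = y, support = support, w = w)
  })
}

# central finite difference of a scalar function
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x))
    e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1L))
}

# held-out q2 of the stage-1 and stage-2 models of a fitted two_step_model
heldout_q2_by_stage <- function(fit, test, descriptors) {
  X <- build_feature_matrix(test, descriptors)
  Xn <- apply_normalizer(fit$normalizer, X)
  p1 <- score_linear(fit$stage1, Xn)
  p2 <- score_linear(fit$stage2, Xn[, fit$selected, drop = FALSE])
  c(
    stage1 = q_squared(test$pic50, p1),
    stage2 = q_squared(test$pic50, p2)
  )
}
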