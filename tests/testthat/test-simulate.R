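# Synthetic-data generators: seeding, shapes, redundancy structure and
# planted-signal consistency.

test_that("peptide generation is seeded and alphabet-clean", {
  p <- simulate_peptides(89, 9, seed = 51)
  expect_identical(nrow(p), 89L)
  expect_true(all(nchar(p$sequence) == 9L))
  chars <- unique(unlist(strsplit(p$sequence, "")))
  expect_true(all(chars %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  expect_identical(p, simulate_peptides(89, 9, seed = 51))
  expect_false(identical(p, simulate_peptides(89, 9, seed = 52)))
  # generators do not disturb the caller's RNG stream
  set.seed(1)
  before <- .Random.seed
  invisible(simulate_peptides(5, 8, seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("descriptor tables have the requested redundancy structure", {
  tab <- simulate_descriptor_table(40, seed = 53, redundancy = 0)
  expect_identical(dim(tab), c(20L, 41L))
  M <- as.matrix(tab[, -1L])
  cc <- stats::cor(M)
  diag(cc) <- 0
  expect_lt(max(abs(cc)), 0.95)

  tab_r <- simulate_descriptor_table(40, seed = 53, redundancy = 0.5)
  M_r <- as.matrix(tab_r[, -1L])
  cc_r <- abs(stats::cor(M_r))
  diag(cc_r) <- 0
  # the copied columns (a 0.5 fraction) correlate >= 0.95 with their source
  n_dup <- sum(apply(cc_r, 2, max) >= 0.95)
  expect_gte(n_dup, 20L)

  # combined dimension law: 643 properties on 9-mers give 6219 columns
  tab643 <- simulate_descriptor_table(643, seed = 54)
  X <- build_feature_matrix(simulate_peptides(4, 9, seed = 1), tab643)
  expect_identical(ncol(X), 6219L)
})

test_that("a noiseless planted signal is recovered exactly on its support", {
  sim <- simulate_regression_dataset(
    n = 60, length = 9,
    descriptors = simulate_descriptor_table(4, seed = 55),
    support_size = 4, effect_size = 1, noise_sd = 0, seed = 55
  )
  X <- build_feature_matrix(sim$train, sim$descriptors)
  norm <- fit_normalizer(X)
  Xn <- apply_normalizer(norm, X)
  cols <- match(sim$truth$informative_features, norm$kept_names)
  expect_false(anyNA(cols))
  refit <- ridge_closed_form(Xn[, cols, drop = FALSE], sim$train$pic50, 0)
  expect_lt(max(abs(refit$w - unname(sim$truth$true_weights))), 1e-6)
  expect_lt(abs(refit$b - sim$truth$true_bias), 1e-6)
})

test_that("stage-1 support recovery degrades monotonically with noise", {
  rate <- vapply(c(0.05, 0.5, 2), function(noise) {
    hits <- vapply(1:5, function(s) {
      sim <- tiny_sim(
        seed = 700 + s, n = 60, length = 6, n_properties = 4,
        support_size = 3, noise_sd = noise
      )
      X <- build_feature_matrix(sim$train, sim$descriptors)
      norm <- fit_normalizer(X)
      m1 <- train_stage1(apply_normalizer(norm, X), sim$train$pic50, 0.05)
      sel <- norm$kept_names[select_features(m1)]
      all(sim$truth$informative_features %in% sel)
    }, logical(1L))
    mean(hits)
  }, numeric(1L))
  expect_true(all(diff(rate) <= 0))
})

test_that("the shifted-test-range scenario shifts only the test targets", {
  sim <- simulate_regression_dataset(
    n = 30, length = 6,
    descriptors = simulate_descriptor_table(3, seed = 56),
    support_size = 2, effect_size = 1, noise_sd = 0.1, seed = 56,
    n_test = 20, test_target_shift = 3
  )
  sim0 <- simulate_regression_dataset(
    n = 30, length = 6,
    descriptors = simulate_descriptor_table(3, seed = 56),
    support_size = 2, effect_size = 1, noise_sd = 0.1, seed = 56,
    n_test = 20, test_target_shift = 0
  )
  expect_identical(sim$train$pic50, sim0$train$pic50)
  expect_equal(sim$test$pic50, sim0$test$pic50 + 3)
})
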