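# Synthetic data in the peptide-QSAR regime the package is built for:
# random fixed-length peptides, synthetic amino-acid descriptor tables
# (optionally with highly correlated redundant columns), and regression
# targets carrying a planted sparse linear signal plus Gaussian noise.
# Everything is a pure function of its seed.

#' Simulate random peptide sequences
#'
#' Draws `n` sequences of the given length uniformly over the 20 standard
#' amino-acid letters.
#'
#' @param n Number of peptides.
#' @param length Peptide length (e.g. 9 for the nona-peptide tasks, 8 for
#'   octo-peptides).
#' @param seed Seed; fixed seed gives identical sequences.
#' @return A tibble with columns `id` (`pep0001`, ...) and `sequence`.
#' @examples
#' simulate_peptides(3, 9, seed = 1)
#' @export
simulate_peptides <- function(n, length, seed) {
  stopifnot(n >= 1, length >= 1)
  with_seed(seed, {
    seqs <- vapply(
      seq_len(n),
      function(i) paste(sample(.aa_standard, length, replace = TRUE),
                        collapse = ""),
      character(1L)
    )
    tibble::tibble(
      id = sprintf("pep%04d", seq_len(n)),
      sequence = seqs
    )
  })
}

#' Simulate an amino-acid descriptor table
#'
#' Property values are drawn from a standard normal per amino acid. A
#' fraction `redundancy` of the property columns are noisy linear copies
#' of earlier columns (pairwise correlation around 0.99), emulating the
#' strong redundancy of large literature-derived physico-chemical
#' property collections, where many properties discriminate amino acids
#' near-equivalently.
#'
#' @param n_properties Number of property columns `P` (the combined
#'   encoding of an `L`-mer then has `(P + 48) * L` features).
#' @param seed Seed.
#' @param redundancy Fraction in `[0, 1]` of columns that are noisy copies
#'   (0 = all independent).
#' @return A tibble with column `aa` (20 rows) and properties
#'   `prop001`, ...
#' @examples
#' simulate_descriptor_table(5, seed = 1)
#' @export
simulate_descriptor_table <- function(n_properties, seed, redundancy = 0) {
  stopifnot(n_properties >= 1, redundancy >= 0, redundancy <= 1)
  with_seed(seed, {
    M <- matrix(rnorm(20L * n_properties), nrow = 20L)
    n_red <- floor(redundancy * n_properties)
    # columns 2..(n_red+1) become noisy copies of uniformly drawn earlier
    # ones; copying sequentially keeps each copy correlated (>= 0.95) with
    # its source even when the source is itself a copy
    if (n_red > 0 && n_properties >= 2) {
      for (j in seq.int(2L, min(n_red + 1L, n_properties))) {
        s <- sample.int(j - 1L, 1L)
        M[, j] <- M[, s] + rnorm(20L, sd = 0.1)
      }
    }
    colnames(M) <- sprintf("prop%03d", seq_len(n_properties))
    dplyr::bind_cols(tibble::tibble(aa = .aa_standard), tibble::as_tibble(M))
  })
}

#' Simulate a peptide regression dataset with a planted sparse signal
#'
#' Generates random peptides, builds their combined normalized feature
#' matrix, plants a sparse weight vector (`support_size` columns with
#' weights of magnitude `effect_size` and random signs) and sets
#' `pic50 = true_bias + x'w_true + noise`. Targets are generated in the
#' normalized feature space so effect sizes are comparable across encoder
#' blocks. Optionally a held-out test split is generated from the same
#' model; `test_target_shift` adds a constant to the test targets only,
#' producing the train/test range mismatch under which q-squared collapses
#' while rank correlation stays informative.
#'
#' @param n Number of training peptides.
#' @param length Peptide length.
#' @param descriptors Descriptor table (e.g. from
#'   [simulate_descriptor_table()]).
#' @param support_size Number of informative features.
#' @param effect_size Magnitude of each planted weight.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Seed.
#' @param n_test Test-set size (0 for none).
#' @param test_target_shift Constant added to test targets (default 0).
#' @param true_bias Intercept of the generating model (default 6, a
#'   typical pIC50 magnitude).
#' @return A list with elements `train` (tibble `id`, `sequence`,
#'   `pic50`), `test` (tibble or `NULL`), `descriptors`, and `truth`: a
#'   list with `informative_features` (names), `informative_indices`
#'   (into the combined feature space), `true_weights` (named, on the
#'   normalized scale), `true_bias`, `noise_sd`, `test_target_shift`.
#' @examples
#' sim <- simulate_regression_dataset(
#'   n = 30, length = 9,
#'   descriptors = simulate_descriptor_table(4, seed = 2),
#'   support_size = 3, effect_size = 1, noise_sd = 0.1, seed = 2
#' )
#' sim$truth$informative_features
#' @export
simulate_regression_dataset <- function(n, length, descriptors,
                                        support_size, effect_size,
                                        noise_sd, seed, n_test = 0,
                                        test_target_shift = 0,
                                        true_bias = 6) {
  stopifnot(support_size >= 1, noise_sd >= 0, n >= 2, n_test >= 0)
  descriptors <- as_descriptor_table(descriptors)
  peptides <- simulate_peptides(n + n_test, length, seed)
  X <- build_feature_matrix(peptides, descriptors)
  if (support_size > ncol(X)) {
    abort(sprintf(
      "support_size (%d) exceeds the combined dimension (%d)",
      support_size, ncol(X)
    ))
  }
  # the generating model lives on the normalized scale of the full sample
  norm <- fit_normalizer(X)
  Xn <- apply_normalizer(norm, X)

  with_seed(seed + 1L, {
    support_kept <- sort(sample.int(ncol(Xn), support_size))
    w_true <- sample(c(-1, 1), support_size, replace = TRUE) * effect_size
    signal <- drop(Xn[, support_kept, drop = FALSE] %*% w_true)
    targets <- true_bias + signal + rnorm(n + n_test, sd = noise_sd)
  })

  is_test <- seq_len(n + n_test) > n
  targets[is_test] <- targets[is_test] + test_target_shift
  data <- dplyr::mutate(peptides, pic50 = targets)

  truth <- list(
    informative_features = norm$kept_names[support_kept],
    informative_indices = unname(norm$kept[support_kept]),
    true_weights = setNames(w_true, norm$kept_names[support_kept]),
    true_bias = true_bias,
    noise_sd = noise_sd,
    test_target_shift = test_target_shift
  )
  list(
    train = data[!is_test, , drop = FALSE],
    test = if (n_test > 0) data[is_test, , drop = FALSE] else NULL,
    descriptors = descriptors,
    truth = truth
  )
}
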