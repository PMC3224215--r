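# The two-step training procedure: L1-regularized stage-1 fit, threshold
# feature selection, L2-regularized stage-2 refit, with each
# regularization strength chosen by k-times repeated n-fold cross
# validation.

# evaluate `code` under `seed` without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Repeated cross-validation fold assignments
#'
#' Randomly partitions `n_samples` indices into `n_folds` near-equal parts
#' (sizes differ by at most 1), `k_repeats` times with independent seeded
#' shuffles. Every sample appears in exactly one validation part per
#' repeat.
#'
#' @param n_samples Number of samples (`>= n_folds`).
#' @param n_folds Number of folds per repeat (`>= 2`).
#' @param k_repeats Number of repeats (`>= 1`).
#' @param seed Master seed; the per-repeat shuffles are drawn sequentially
#'   from the stream it initializes, so a fixed seed reproduces the exact
#'   assignment.
#' @return A tibble with columns `repeat_id`, `fold`, `sample`, one row
#'   per (repeat, sample).
#' @examples
#' folds <- make_folds(10, n_folds = 5, k_repeats = 2, seed = 1)
#' table(folds$repeat_id, folds$fold) # all parts of size 2
#' @export
make_folds <- function(n_samples, n_folds, k_repeats, seed) {
  if (n_folds > n_samples) {
    abort(sprintf(
      "n_folds (%d) cannot exceed n_samples (%d)", n_folds, n_samples
    ))
  }
  stopifnot(n_folds >= 2, k_repeats >= 1)
  with_seed(seed, {
    purrr::map_dfr(seq_len(k_repeats), function(r) {
      shuffled <- sample.int(n_samples)
      tibble::tibble(
        repeat_id = r,
        fold = rep(seq_len(n_folds), length.out = n_samples),
        sample = shuffled
      )
    })
  }) |>
    dplyr::arrange(.data$repeat_id, .data$fold, .data$sample)
}

validation_error <- function(pred, obs, loss, validation) {
  if (validation == "q2") {
    1 - q_squared(obs, pred)
  } else if (loss == "soft") {
    mean(soft_loss(pred, obs))
  } else {
    mean((pred - obs)^2)
  }
}

#' Choose a regularization strength by repeated k x n-fold cross validation
#'
#' For every (repeat, fold, candidate) cell: a normalizer is fitted on the
#' fold-training portion (avoiding information leakage; see
#' `normalization`), an Rprop fit is run at the candidate strength, and
#' the validation error is measured on the held-out part. Errors are
#' averaged over all `k_repeats * n_folds` cells and the candidate with
#' the smallest average wins; ties go to the larger (more conservative)
#' lambda.
#'
#' @param X Raw (un-normalized) numeric feature matrix.
#' @param targets Numeric vector of measured values.
#' @param candidates Non-empty numeric vector of lambda candidates.
#' @param stage 1 (candidates are L1 strengths, `lambda2 = 0`) or 2
#'   (candidates are L2 strengths, `lambda1 = 0`).
#' @param k_repeats,n_folds Repeats and folds (defaults 5 and 10, the
#'   protocol this package follows throughout).
#' @param seed Seed for the fold shuffles.
#' @param opt An [rprop_config()]; the default caps each of the
#'   `k_repeats * n_folds * length(candidates)` fits at 2000 iterations —
#'   a coarser budget than a standalone fit, which is enough to rank the
#'   candidates while keeping the selection loop fast.
#' @param loss Training loss, `"soft"` (default) or `"squared"`.
#' @param sample_weights Optional per-sample weights.
#' @param normalization `"per-fold"` (default; refit inside each fold) or
#'   `"global"` (one normalizer on all of `X`, the possibly-leaky
#'   alternative).
#' @param validation `"loss"` (default; mean training-loss function on the
#'   held-out part, keeping selection consistent with the objective) or
#'   `"q2"` (uses `1 - q_squared`).
#' @return A `cv_result` object: per-fold errors (tibble), a per-candidate
#'   summary, and `chosen_lambda`.
#' @export
cross_validate_lambda <- function(X, targets, candidates, stage,
                                  k_repeats = 5, n_folds = 10, seed = 1,
                                  opt = rprop_config(max_iter = 2000L),
                                  loss = "soft",
                                  sample_weights = NULL,
                                  normalization = c("per-fold", "global"),
                                  validation = c("loss", "q2")) {
  normalization <- match.arg(normalization)
  validation <- match.arg(validation)
  stopifnot(stage %in% c(1, 2))
  candidates <- as.double(candidates)
  if (length(candidates) == 0L) abort("candidates must be non-empty")
  X <- as.matrix(X)
  n <- nrow(X)
  folds <- make_folds(n, n_folds, k_repeats, seed)
  cells <- dplyr::distinct(folds, .data$repeat_id, .data$fold)

  global_norm <- if (normalization == "global") fit_normalizer(X) else NULL

  per_fold <- purrr::pmap_dfr(cells, function(repeat_id, fold) {
    va <- folds$sample[folds$repeat_id == repeat_id & folds$fold == fold]
    tr <- setdiff(seq_len(n), va)
    if (length(tr) < 2L) {
      abort("a fold-training portion has fewer than 2 samples")
    }
    norm <- global_norm %||% fit_normalizer(X[tr, , drop = FALSE])
    Xtr <- apply_normalizer(norm, X[tr, , drop = FALSE])
    Xva <- apply_normalizer(norm, X[va, , drop = FALSE])
    mtr <- targets[tr]
    mva <- targets[va]
    mu_tr <- if (is.null(sample_weights)) NULL else sample_weights[tr]
    err <- vapply(candidates, function(lambda) {
      cfg <- objective_config(
        lambda1 = if (stage == 1) lambda else 0,
        lambda2 = if (stage == 2) lambda else 0,
        loss = loss, sample_weights = mu_tr
      )
      fit <- rprop_minimize(Xtr, mtr, cfg, opt)
      validation_error(score_linear(fit$model, Xva), mva, loss, validation)
    }, numeric(1L))
    tibble::tibble(
      repeat_id = repeat_id, fold = fold,
      lambda = candidates, error = err, n_valid = length(va)
    )
  })

  summary <- per_fold |>
    dplyr::group_by(.data$lambda) |>
    dplyr::summarise(mean_error = mean(.data$error), .groups = "drop") |>
    dplyr::arrange(.data$lambda)
  best <- min(summary$mean_error)
  chosen <- max(summary$lambda[summary$mean_error == best])

  structure(
    list(
      stage = stage, candidates = sort(candidates),
      per_fold = per_fold, summary = summary, chosen_lambda = chosen,
      k_repeats = k_repeats, n_folds = n_folds, seed = seed,
      loss = loss, normalization = normalization, validation = validation
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> stage %d, %d x %d-fold CV over %d candidates; chosen lambda%d = %g\n",
    x$stage, x$k_repeats, x$n_folds, length(x$candidates), x$stage,
    x$chosen_lambda
  ))
  invisible(x)
}

#' Stage-1 fit: L1-regularized robust regression
#'
#' Runs [rprop_minimize()] with an L1 penalty of strength `lambda1` (and
#' no L2 term). Under the L1 penalty the weights of irrelevant and
#' redundant features are driven into a near-zero band, which is what the
#' subsequent threshold selection exploits.
#'
#' @param X Normalized feature matrix.
#' @param targets Measured values.
#' @param lambda1 L1 strength in `[0, 1)`.
#' @param opt An [rprop_config()].
#' @param loss Training loss (default `"soft"`).
#' @param sample_weights Optional per-sample weights.
#' @return A [linear_model()] over all columns of `X`.
#' @export
train_stage1 <- function(X, targets, lambda1, opt = rprop_config(),
                         loss = "soft", sample_weights = NULL) {
  cfg <- objective_config(
    lambda1 = lambda1, lambda2 = 0,
    loss = loss, sample_weights = sample_weights
  )
  rprop_minimize(X, targets, cfg, opt)$model
}

#' Threshold-based feature selection
#'
#' Returns the (1-based, sorted) indices of weights with
#' `|w_i| >= threshold`. Rprop does not set weights exactly to zero, so
#' features whose weights the L1 penalty has pushed below the small
#' threshold (default `1e-8`) are treated as switched off.
#'
#' @param model A [linear_model()], typically a stage-1 fit.
#' @param threshold Positive selection threshold (default `1e-8`).
#' @return Sorted integer vector of selected column indices.
#' @examples
#' select_features(linear_model(c(0.5, 1e-9, -0.3))) # 1 and 3
#' @export
select_features <- function(model, threshold = 1e-8) {
  stopifnot(inherits(model, "linear_model"), threshold > 0)
  which(abs(model$w) >= threshold)
}

#' Stage-2 fit: L2-regularized refit on the selected features
#'
#' Restricts `X` to the selected columns and runs [rprop_minimize()] with
#' an L2 penalty of strength `lambda2` (and no L1 term). The milder ridge
#' refit on the surviving features generally improves prediction over the
#' stage-1 model.
#'
#' @inheritParams train_stage1
#' @param selected Non-empty integer vector of column indices from
#'   [select_features()].
#' @param lambda2 L2 strength in `[0, 1)`.
#' @return A [linear_model()] with `length(selected)` weights.
#' @export
train_stage2 <- function(X, targets, selected, lambda2,
                         opt = rprop_config(), loss = "soft",
                         sample_weights = NULL) {
  if (length(selected) == 0L) {
    abort("no features selected; lower lambda1 or the selection threshold")
  }
  cfg <- objective_config(
    lambda1 = 0, lambda2 = lambda2,
    loss = loss, sample_weights = sample_weights
  )
  rprop_minimize(X[, selected, drop = FALSE], targets, cfg, opt)$model
}

#' Configuration of the two-step pipeline
#'
#' Defaults follow the protocol this package is built around: candidate
#' grids `lambda1` in {0.001, 0.005, 0.01, 0.05, 0.08, 0.1, 0.2, 0.3} and
#' `lambda2` in {0.0001, 0.001, 0.01, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7,
#' 0.8, 0.9, 0.93}, five repeats of ten-fold cross validation, and the
#' `1e-8` selection threshold.
#'
#' @param lambda1_grid,lambda2_grid Candidate regularization strengths.
#' @param k_repeats,n_folds Cross-validation repeats and folds.
#' @param threshold Feature-selection threshold on `|w|`.
#' @param seed Master seed; stage-1 CV uses `seed`, stage-2 CV uses
#'   `seed + 1`.
#' @param optimizer An [rprop_config()] for the two final full-training
#'   fits, run to convergence so the `1e-8` selection threshold acts on
#'   the annealed L1 solution.
#' @param cv_optimizer An [rprop_config()] for the fits inside the two
#'   cross-validation loops; the default 2000-iteration budget is enough
#'   to rank candidate lambdas and keeps model selection fast.
#' @param loss Training loss, `"soft"` (default) or `"squared"`.
#' @param normalization,validation See [cross_validate_lambda()].
#' @return A `run_config` list.
#' @export
run_config <- function(lambda1_grid = c(0.001, 0.005, 0.01, 0.05, 0.08, 0.1, 0.2, 0.3),
                       lambda2_grid = c(0.0001, 0.001, 0.01, 0.1, 0.2, 0.3,
                                        0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.93),
                       k_repeats = 5, n_folds = 10, threshold = 1e-8,
                       seed = 1, optimizer = rprop_config(),
                       cv_optimizer = rprop_config(max_iter = 2000L),
                       loss = "soft",
                       normalization = "per-fold", validation = "loss") {
  stopifnot(
    length(lambda1_grid) >= 1, length(lambda2_grid) >= 1,
    all(lambda1_grid >= 0 & lambda1_grid < 1),
    all(lambda2_grid >= 0 & lambda2_grid < 1),
    threshold > 0
  )
  structure(
    list(
      lambda1_grid = as.double(lambda1_grid),
      lambda2_grid = as.double(lambda2_grid),
      k_repeats = k_repeats, n_folds = n_folds, threshold = threshold,
      seed = as.integer(seed), optimizer = optimizer,
      cv_optimizer = cv_optimizer, loss = loss,
      normalization = normalization, validation = validation
    ),
    class = "run_config"
  )
}

#' Fit the two-step L1/L2 model
#'
#' The full training procedure on a peptide dataset with measured pIC50
#' values:
#' 1. encode all peptides ([build_feature_matrix()]) and fit the
#'    normalizer on the whole training set;
#' 2. choose `lambda1` by repeated n-fold CV over `lambda1_grid`;
#' 3. stage-1 L1 fit on the full training set; keep features with
#'    `|w| >= threshold`;
#' 4. choose `lambda2` by repeated n-fold CV on the selected submatrix;
#' 5. stage-2 L2 refit on the full training set, restricted to the
#'    selected features.
#'
#' The result is fully determined by `(data, descriptors, config)`: Rprop
#' is deterministic and all fold shuffles derive from `config$seed`.
#'
#' @param data Peptide data frame with columns `id`, `sequence`, `pic50`.
#' @param descriptors Descriptor table (see [encode_physchem()]).
#' @param config A [run_config()].
#' @return A `two_step_model` object; see [predict.two_step_model()],
#'   [tidy.two_step_model()], [glance.two_step_model()].
#' @examples
#' \donttest{
#' sim <- simulate_regression_dataset(
#'   n = 40, length = 9,
#'   descriptors = simulate_descriptor_table(4, seed = 7),
#'   support_size = 3, effect_size = 1, noise_sd = 0.1, seed = 7
#' )
#' fit <- fit_two_step(sim$train, sim$descriptors,
#'   run_config(k_repeats = 1, n_folds = 5, seed = 7)
#' )
#' glance(fit)
#' }
#' @export
fit_two_step <- function(data, descriptors, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  data <- validate_peptide_data(data, require_targets = TRUE)
  targets <- data$pic50
  descriptors <- as_descriptor_table(descriptors)

  X_raw <- build_feature_matrix(data, descriptors)
  feature_info <- attr(X_raw, "feature_info")
  norm <- fit_normalizer(X_raw)
  Xn <- apply_normalizer(norm, X_raw)

  cv1 <- cross_validate_lambda(
    X_raw, targets, config$lambda1_grid,
    stage = 1,
    k_repeats = config$k_repeats, n_folds = config$n_folds,
    seed = config$seed, opt = config$cv_optimizer, loss = config$loss,
    normalization = config$normalization, validation = config$validation
  )
  stage1 <- train_stage1(Xn, targets, cv1$chosen_lambda,
    opt = config$optimizer, loss = config$loss
  )
  selected <- select_features(stage1, config$threshold)
  if (length(selected) == 0L) {
    abort("stage 1 selected no features; lower lambda1 or the threshold")
  }

  cv2 <- cross_validate_lambda(
    X_raw[, norm$kept[selected], drop = FALSE], targets,
    config$lambda2_grid,
    stage = 2,
    k_repeats = config$k_repeats, n_folds = config$n_folds,
    seed = config$seed + 1L, opt = config$cv_optimizer, loss = config$loss,
    normalization = config$normalization, validation = config$validation
  )
  stage2 <- train_stage2(Xn, targets, selected, cv2$chosen_lambda,
    opt = config$optimizer, loss = config$loss
  )

  structure(
    list(
      normalizer = norm,
      stage1 = stage1,
      selected = selected,
      selected_features = norm$kept_names[selected],
      stage2 = stage2,
      lambda1 = cv1$chosen_lambda,
      lambda2 = cv2$chosen_lambda,
      threshold = config$threshold,
      cv1 = cv1, cv2 = cv2,
      config = config,
      descriptors = descriptors,
      peptide_length = nchar(data$sequence[1L]),
      feature_info = feature_info,
      provenance = list(
        n_train = nrow(data),
        d_initial = ncol(X_raw),
        d_kept = length(norm$kept),
        d_selected = length(selected),
        seed = config$seed,
        data_hash = rlang::hash(list(data$id, data$sequence, targets))
      )
    ),
    class = "two_step_model"
  )
}

#' @export
print.two_step_model <- function(x, ...) {
  p <- x$provenance
  cat("<two_step_model>\n")
  cat(sprintf(
    "  %d peptides of length %d; features: %d initial -> %d after normalization -> %d selected\n",
    p$n_train, x$peptide_length, p$d_initial, p$d_kept, p$d_selected
  ))
  cat(sprintf(
    "  stage 1: lambda1 = %g (CV); stage 2: lambda2 = %g (CV); threshold %g\n",
    x$lambda1, x$lambda2, x$threshold
  ))
  invisible(x)
}

#' Predict pIC50 values with a fitted two-step model
#'
#' Encodes the new peptides, applies the stored training normalizer,
#' restricts to the selected features and evaluates the stage-2 scoring
#' function.
#'
#' @param object A `two_step_model` from [fit_two_step()].
#' @param new_data Peptide data frame with columns `id` and `sequence`
#'   (sequences must have the training length).
#' @param descriptors Optional descriptor table; defaults to the table
#'   stored in the model.
#' @param ... Unused.
#' @return A tibble with columns `id` and `predicted_pic50`.
#' @export
predict.two_step_model <- function(object, new_data, descriptors = NULL, ...) {
  new_data <- validate_peptide_data(new_data)
  L <- nchar(new_data$sequence[1L])
  if (L != object$peptide_length) {
    abort(sprintf(
      "model was trained on %d-mers but new sequences have length %d",
      object$peptide_length, L
    ))
  }
  X <- build_feature_matrix(new_data, descriptors %||% object$descriptors)
  if (ncol(X) != object$provenance$d_initial) {
    abort("descriptor table does not match the one used in training")
  }
  Xn <- apply_normalizer(object$normalizer, X)
  pred <- score_linear(object$stage2, Xn[, object$selected, drop = FALSE])
  tibble::tibble(id = new_data$id, predicted_pic50 = unname(pred))
}
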