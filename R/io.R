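# Delimited-text readers/writers for peptide tables, descriptor tables,
# feature matrices and predictions, plus JSON model serialization.

read_tsv_strict <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
}

#' Read a peptide table
#'
#' Tab-separated with a header `id<TAB>sequence[<TAB>pic50]`. All
#' sequences must share one length and use the 20 standard letters plus
#' the placeholders `*`, `B`, `X`, `Z`; violations are reported with the
#' offending file line (header = line 1).
#'
#' @param path Path to the TSV file.
#' @param has_targets If `TRUE` (default) a complete numeric `pic50`
#'   column is required.
#' @return A tibble with columns `id`, `sequence` and (if present)
#'   `pic50`.
#' @export
read_peptide_table <- function(path, has_targets = TRUE) {
  tab <- read_tsv_strict(path)
  if (!all(c("id", "sequence") %in% names(tab))) {
    abort(sprintf("%s: header must contain 'id' and 'sequence'", path))
  }
  line <- function(i) i + 1L # header occupies line 1
  dup <- which(duplicated(tab$id))
  if (length(dup) > 0L) {
    abort(sprintf(
      "%s line %d: duplicate id '%s'", path, line(dup[1L]), tab$id[dup[1L]]
    ))
  }
  len <- nchar(tab$sequence)
  if (length(unique(len)) > 1L) {
    off <- which(len != len[1L])[1L]
    abort(sprintf(
      "%s line %d: sequence length %d differs from %d",
      path, line(off), len[off], len[1L]
    ))
  }
  ok <- strsplit(tab$sequence, "", fixed = TRUE) |>
    vapply(function(r) all(r %in% .sparse_alphabet), logical(1L))
  if (!all(ok)) {
    off <- which(!ok)[1L]
    abort(sprintf(
      "%s line %d: sequence '%s' contains a non-amino-acid character",
      path, line(off), tab$sequence[off]
    ))
  }
  if ("pic50" %in% names(tab)) {
    val <- suppressWarnings(as.double(tab$pic50))
    bad <- which(is.na(val) & !is.na(tab$pic50))
    if (length(bad) > 0L) {
      abort(sprintf(
        "%s line %d: pic50 value '%s' is not numeric",
        path, line(bad[1L]), tab$pic50[bad[1L]]
      ))
    }
    if (has_targets && anyNA(val)) {
      abort(sprintf(
        "%s line %d: missing pic50 value", path, line(which(is.na(val))[1L])
      ))
    }
    tab$pic50 <- val
  } else if (has_targets) {
    abort(sprintf("%s: no 'pic50' column but targets were required", path))
  }
  tab
}

#' Read peptide sequences from a FASTA file
#'
#' Record identifiers become `id`, sequences `sequence`. Targets can be
#' joined on `id` from a data frame or a two-column TSV (`id`, `pic50`).
#' Requires the Biostrings package.
#'
#' @param path Path to the FASTA file.
#' @param targets Optional data frame with columns `id` and `pic50`, or a
#'   path to such a TSV.
#' @return A tibble with columns `id`, `sequence` and (if targets given)
#'   `pic50`.
#' @export
read_peptide_fasta <- function(path, targets = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTA requires the Biostrings package")
  }
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  seqs <- Biostrings::readAAStringSet(path)
  out <- tibble::tibble(
    id = sub("\\s.*$", "", names(seqs)),
    sequence = unname(as.character(seqs))
  )
  if (!is.null(targets)) {
    if (is.character(targets)) {
      targets <- read_tsv_strict(targets)
      targets$pic50 <- as.double(targets$pic50)
    }
    stopifnot(all(c("id", "pic50") %in% names(targets)))
    missing <- setdiff(out$id, targets$id)
    if (length(missing) > 0L) {
      abort(sprintf("no target value for id '%s'", missing[1L]))
    }
    out <- dplyr::left_join(out,
      dplyr::select(tibble::as_tibble(targets), "id", "pic50"),
      by = "id"
    )
  }
  validate_peptide_data(out, require_targets = !is.null(targets))
}

#' Read an amino-acid descriptor table
#'
#' Tab-separated; first column the amino-acid one-letter code, remaining
#' columns named numeric properties. All 20 standard amino acids must be
#' present.
#'
#' @param path Path to the TSV file.
#' @return A descriptor tibble (column `aa` plus `P` property columns),
#'   rows ordered by the canonical alphabet.
#' @export
read_descriptor_table <- function(path) {
  tab <- read_tsv_strict(path)
  if (ncol(tab) < 2L) {
    abort(sprintf("%s: descriptor table needs at least one property column", path))
  }
  names(tab)[1L] <- "aa"
  for (j in seq.int(2L, ncol(tab))) {
    val <- suppressWarnings(as.double(tab[[j]]))
    bad <- which(is.na(val) & !is.na(tab[[j]]))
    if (length(bad) > 0L) {
      abort(sprintf(
        "%s line %d: column '%s' has non-numeric value '%s'",
        path, bad[1L] + 1L, names(tab)[j], tab[[j]][bad[1L]]
      ))
    }
    tab[[j]] <- val
  }
  as_descriptor_table(tab)
}

#' Write a table as TSV
#'
#' @param data Data frame (peptides, descriptors or predictions).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(data, path) {
  readr::write_tsv(data, path, progress = FALSE)
  invisible(path)
}

#' Export a feature matrix as TSV
#'
#' Writes an `id` column followed by one named column per feature.
#'
#' @param X Feature matrix from [build_feature_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(X, path) {
  out <- tibble::as_tibble(X, .name_repair = "minimal")
  out <- dplyr::bind_cols(
    tibble::tibble(id = rownames(X) %||% as.character(seq_len(nrow(X)))),
    out
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

.model_format_version <- "1.0"

#' Save a fitted two-step model as JSON
#'
#' The file records everything needed to reproduce predictions exactly:
#' normalizer statistics, both weight vectors, the selected feature names
#' and indices, the chosen regularization strengths, the selection
#' threshold, seed, optimizer settings and the descriptor table. Numbers
#' are written at full precision, so a save/load round trip reproduces
#' predictions bit for bit.
#'
#' @param model A `two_step_model` from [fit_two_step()].
#' @param path Output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "two_step_model"))
  payload <- list(
    format = "twostepQSAR-model",
    version = .model_format_version,
    peptide_length = model$peptide_length,
    lambda1 = model$lambda1,
    lambda2 = model$lambda2,
    threshold = model$threshold,
    loss = model$config$loss,
    normalization = model$config$normalization,
    validation = model$config$validation,
    seed = model$config$seed,
    optimizer = unclass(model$config$optimizer),
    cv_optimizer = unclass(model$config$cv_optimizer),
    normalizer = list(
      kept = model$normalizer$kept,
      kept_names = model$normalizer$kept_names,
      means = model$normalizer$means,
      sds = model$normalizer$sds
    ),
    stage1 = list(w = model$stage1$w, b = model$stage1$b),
    selected = model$selected,
    selected_features = model$selected_features,
    stage2 = list(w = model$stage2$w, b = model$stage2$b),
    descriptors = model$descriptors,
    provenance = model$provenance
  )
  # I(17) significant digits: doubles survive the round trip bit for bit
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a two-step model saved by [save_model()]
#'
#' @param path Path to the model JSON file.
#' @return A `two_step_model` (prediction-complete; cross-validation
#'   traces are not stored in the file).
#' @export
load_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) {
      abort(sprintf("%s: not a valid model file (%s)", path, conditionMessage(e)))
    }
  )
  if (!identical(payload$format, "twostepQSAR-model")) {
    abort(sprintf("%s: not a twostepQSAR model file", path))
  }
  if (!identical(payload$version, .model_format_version)) {
    abort(sprintf(
      "%s: model format version '%s' is not supported (expected '%s')",
      path, payload$version %||% "?", .model_format_version
    ))
  }
  norm <- structure(
    list(
      kept = as.integer(payload$normalizer$kept),
      kept_names = payload$normalizer$kept_names,
      means = payload$normalizer$means,
      sds = payload$normalizer$sds
    ),
    class = "feature_normalizer"
  )
  cfg <- run_config(
    k_repeats = 0L, n_folds = 0L, threshold = payload$threshold,
    seed = payload$seed,
    optimizer = do.call(rprop_config, payload$optimizer[
      c("eta_plus", "eta_minus", "delta0", "delta_min", "delta_max",
        "max_iter", "tol")
    ]),
    cv_optimizer = do.call(rprop_config, payload$cv_optimizer[
      c("eta_plus", "eta_minus", "delta0", "delta_min", "delta_max",
        "max_iter", "tol")
    ]),
    loss = payload$loss, normalization = payload$normalization,
    validation = payload$validation
  )
  structure(
    list(
      normalizer = norm,
      stage1 = linear_model(payload$stage1$w, payload$stage1$b),
      selected = as.integer(payload$selected),
      selected_features = payload$selected_features,
      stage2 = linear_model(payload$stage2$w, payload$stage2$b),
      lambda1 = payload$lambda1,
      lambda2 = payload$lambda2,
      threshold = payload$threshold,
      cv1 = NULL, cv2 = NULL,
      config = cfg,
      descriptors = as_descriptor_table(payload$descriptors),
      peptide_length = as.integer(payload$peptide_length),
      feature_info = NULL,
      provenance = payload$provenance
    ),
    class = "two_step_model"
  )
}
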