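# Peptide feature encoders: physico-chemical descriptors, one-hot (sparse)
# and BLOSUM62 rows, concatenated per peptide, plus the training-set
# normalizer that drops zero-variance columns and standardizes the rest.

.aa_standard <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
.aa_placeholder <- c("*", "B", "X", "Z")
# component order of one sparse sub-vector: 20 standard letters, then the
# gap/ambiguity codes
.sparse_alphabet <- c(.aa_standard, .aa_placeholder)

split_residues <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  strsplit(sequence, "", fixed = TRUE)[[1]]
}

check_residues <- function(residues, allowed, context) {
  bad <- which(!(residues %in% allowed))
  if (length(bad) > 0L) {
    abort(sprintf(
      "%s: unknown residue '%s' at position %d",
      context, residues[bad[1L]], bad[1L]
    ))
  }
  invisible(residues)
}

#' One-hot (sparse) encoding of a peptide sequence
#'
#' Represents each residue by a 24-component sub-vector: the 20 standard
#' amino acids in the order `ACDEFGHIKLMNPQRSTVWY`, followed by the
#' placeholder codes `*`, `B`, `X`, `Z`. Exactly one component per residue
#' is 1, the rest 0; sub-vectors are concatenated in sequence order, so a
#' peptide of length `L` yields `24 * L` features.
#'
#' @param sequence A single peptide string over the 20 standard amino-acid
#'   letters plus the placeholders `*`, `B`, `X`, `Z`.
#' @return A named numeric vector of length `24 * nchar(sequence)`.
#' @examples
#' v <- encode_sparse("ACDEFGHIK")
#' length(v) # 216
#' sum(v)    # one unit entry per residue
#' @seealso [encode_blosum62()], [encode_physchem()], [build_feature_matrix()]
#' @export
encode_sparse <- function(sequence) {
  res <- split_residues(sequence)
  check_residues(res, .sparse_alphabet, "sparse encoding")
  L <- length(res)
  out <- numeric(24L * L)
  idx <- match(res, .sparse_alphabet)
  out[24L * (seq_len(L) - 1L) + idx] <- 1
  names(out) <- sparse_feature_names(L)
  out
}

#' BLOSUM62 encoding of a peptide sequence
#'
#' Each residue contributes its 24-entry row of the BLOSUM62 substitution
#' matrix (NCBI dialect, columns ordered `ARNDCQEGHILKMFPSTWYVBZX*`), so
#' chemically similar residues receive similar sub-vectors. A peptide of
#' length `L` yields `24 * L` features.
#'
#' @inheritParams encode_sparse
#' @return A named numeric vector of length `24 * nchar(sequence)`.
#' @examples
#' v <- encode_blosum62("AC")
#' v[["blosum_p1_A"]] # 4, the BLOSUM62 diagonal for alanine
#' @export
encode_blosum62 <- function(sequence) {
  res <- split_residues(sequence)
  B <- blosum62_matrix()
  check_residues(res, rownames(B), "BLOSUM62 encoding")
  out <- as.numeric(t(B[res, , drop = FALSE]))
  names(out) <- blosum_feature_names(length(res))
  out
}

#' Physico-chemical encoding of a peptide sequence
#'
#' Each residue contributes the `P` property values recorded for its letter
#' in a descriptor table, giving `P * L` features for a peptide of length
#' `L`. Placeholder letters (`*`, `B`, `X`, `Z`) carry no property values
#' and are rejected.
#'
#' @inheritParams encode_sparse
#' @param descriptors A descriptor table: a data frame whose first column
#'   (`aa`) holds the 20 standard amino-acid one-letter codes and whose
#'   remaining numeric columns are named properties (see
#'   [read_descriptor_table()] / [simulate_descriptor_table()]).
#' @return A named numeric vector of length `P * nchar(sequence)`.
#' @export
encode_physchem <- function(sequence, descriptors) {
  tab <- as_descriptor_table(descriptors)
  res <- split_residues(sequence)
  check_residues(res, tab$aa, "physico-chemical encoding")
  M <- as.matrix(tab[, -1L, drop = FALSE]) # 20 x P
  rownames(M) <- tab$aa
  out <- as.numeric(t(M[res, , drop = FALSE]))
  names(out) <- phys_feature_names(length(res), colnames(M))
  out
}

sparse_feature_names <- function(L) {
  comp <- .sparse_alphabet
  paste0("sparse_p", rep(seq_len(L), each = 24L), "_", comp)
}

blosum_feature_names <- function(L) {
  comp <- .blosum62_order
  paste0("blosum_p", rep(seq_len(L), each = 24L), "_", comp)
}

phys_feature_names <- function(L, properties) {
  paste0(
    "phys_p", rep(seq_len(L), each = length(properties)), "_",
    properties
  )
}

validate_peptide_data <- function(data, require_targets = FALSE) {
  if (!is.data.frame(data) || nrow(data) == 0L) {
    abort("peptide data must be a data frame with at least one row")
  }
  if (!all(c("id", "sequence") %in% names(data))) {
    abort("peptide data needs columns 'id' and 'sequence'")
  }
  data <- tibble::as_tibble(data)
  data$id <- as.character(data$id)
  if (anyDuplicated(data$id)) {
    abort(sprintf(
      "duplicate peptide id: '%s'",
      data$id[duplicated(data$id)][1L]
    ))
  }
  len <- nchar(data$sequence)
  if (length(unique(len)) != 1L) {
    off <- which(len != len[1L])[1L]
    abort(sprintf(
      "all sequences must share one length: row %d ('%s') has length %d, expected %d",
      off, data$id[off], len[off], len[1L]
    ))
  }
  if (require_targets) {
    if (!("pic50" %in% names(data)) || anyNA(data$pic50)) {
      abort("peptide data needs a complete numeric 'pic50' column for training")
    }
    data$pic50 <- as.double(data$pic50)
  }
  data
}

as_descriptor_table <- function(descriptors) {
  if (!is.data.frame(descriptors)) {
    abort("descriptors must be a data frame (first column 'aa', then properties)")
  }
  tab <- tibble::as_tibble(descriptors)
  if (names(tab)[1L] != "aa") names(tab)[1L] <- "aa"
  tab$aa <- as.character(tab$aa)
  missing <- setdiff(.aa_standard, tab$aa)
  if (length(missing) > 0L) {
    abort(sprintf(
      "descriptor table is missing amino acid(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  if (ncol(tab) < 2L) abort("descriptor table has no property columns")
  num <- vapply(tab[-1L], is.numeric, logical(1L))
  if (!all(num)) {
    abort(sprintf(
      "descriptor column '%s' is not numeric",
      names(tab)[-1L][!num][1L]
    ))
  }
  tab[match(.aa_standard, tab$aa), , drop = FALSE]
}

#' Build the combined feature matrix for a peptide dataset
#'
#' Encodes every peptide with the three encoders and concatenates the
#' blocks in the fixed order physico-chemical, sparse, BLOSUM62, giving
#' `d = (P + 48) * L` columns for peptides of length `L` and a descriptor
#' table with `P` properties (e.g. 6219 columns for 9-mers with the
#' 643-property table, 5528 for 8-mers).
#'
#' @param data A peptide data frame with columns `id` and `sequence`
#'   (targets, if present, are carried along unchanged elsewhere).
#' @param descriptors A descriptor table (see [encode_physchem()]).
#' @return A numeric matrix with one row per peptide (rownames = ids) and
#'   named feature columns; the column metadata is attached as attribute
#'   `"feature_info"`, a tibble with columns `feature`, `block`,
#'   `position`, `component`.
#' @examples
#' tab <- simulate_descriptor_table(n_properties = 3, seed = 1)
#' X <- build_feature_matrix(
#'   tibble::tibble(id = c("a", "b"), sequence = c("AC", "CA")), tab
#' )
#' dim(X) # 2 x (3 + 48) * 2 = 2 x 102
#' @export
build_feature_matrix <- function(data, descriptors) {
  data <- validate_peptide_data(data)
  tab <- as_descriptor_table(descriptors)
  L <- nchar(data$sequence[1L])
  props <- names(tab)[-1L]

  phys <- t(vapply(
    data$sequence, encode_physchem,
    numeric(length(props) * L),
    descriptors = tab
  ))
  sparse <- t(vapply(data$sequence, encode_sparse, numeric(24L * L)))
  blosum <- t(vapply(data$sequence, encode_blosum62, numeric(24L * L)))

  X <- cbind(phys, sparse, blosum)
  rownames(X) <- data$id
  colnames(X) <- c(
    phys_feature_names(L, props),
    sparse_feature_names(L),
    blosum_feature_names(L)
  )
  attr(X, "feature_info") <- feature_info_from_names(colnames(X))
  X
}

feature_info_from_names <- function(feature_names) {
  parts <- strsplit(feature_names, "_", fixed = TRUE)
  tibble::tibble(
    feature = feature_names,
    block = vapply(parts, `[[`, character(1L), 1L),
    position = as.integer(sub("^p", "", vapply(parts, `[[`, character(1L), 2L))),
    component = vapply(
      parts,
      function(p) paste(p[-(1:2)], collapse = "_"),
      character(1L)
    )
  )
}

#' Fit a training-set feature normalizer
#'
#' Columns whose training standard deviation (population convention,
#' denominator `n`) falls below `tol` carry no information and are dropped;
#' the remaining columns are recorded with their training means and
#' standard deviations so that train and test data are shifted and scaled
#' identically.
#'
#' @param X A numeric feature matrix with at least two rows.
#' @param tol Zero-variance tolerance on the standard deviation
#'   (default `1e-12`); absorbs floating-point noise in constant columns.
#' @return A `feature_normalizer` object with fields `kept` (column
#'   indices), `kept_names`, `means` and `sds`.
#' @examples
#' X <- cbind(a = c(0, 0, 0), b = c(1, 2, 3))
#' norm <- fit_normalizer(X)
#' norm$kept_names # "b": the constant column is dropped
#' @export
fit_normalizer <- function(X, tol = 1e-12) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) abort("need at least 2 samples to fit a normalizer")
  means <- colMeans(X)
  # population standard deviation (denominator n)
  sds <- sqrt(colMeans(X^2) - means^2)
  sds[sds < 0 | is.na(sds)] <- 0 # guard tiny negative round-off
  kept <- unname(which(sds >= tol))
  structure(
    list(
      kept = kept,
      kept_names = colnames(X)[kept],
      means = unname(means[kept]),
      sds = unname(sds[kept])
    ),
    class = "feature_normalizer"
  )
}

#' Apply a fitted normalizer
#'
#' Restricts `X` to the columns kept at fitting time and standardizes each
#' with the stored training mean and standard deviation. Applied to the
#' fitting matrix itself, every column comes out with mean 0 and standard
#' deviation 1; test columns are governed entirely by the training
#' parameters (a column constant in the test set is not re-dropped).
#'
#' @param norm A `feature_normalizer` from [fit_normalizer()].
#' @param X A numeric matrix with at least `max(norm$kept)` columns.
#' @return The standardized matrix restricted to the kept columns.
#' @export
apply_normalizer <- function(norm, X) {
  stopifnot(inherits(norm, "feature_normalizer"))
  X <- as.matrix(X)
  if (ncol(X) < max(norm$kept, 0L)) {
    abort(sprintf(
      "matrix has %d columns but the normalizer was fitted on at least %d",
      ncol(X), max(norm$kept)
    ))
  }
  if (!is.null(colnames(X)) && !is.null(norm$kept_names) &&
    !identical(colnames(X)[norm$kept], norm$kept_names)) {
    abort("column names do not match the columns the normalizer was fitted on")
  }
  out <- sweep(X[, norm$kept, drop = FALSE], 2L, norm$means, "-")
  out <- sweep(out, 2L, norm$sds, "/")
  out
}

#' @export
print.feature_normalizer <- function(x, ...) {
  cat(sprintf(
    "<feature_normalizer> %d columns kept (means/sds from training set)\n",
    length(x$kept)
  ))
  invisible(x)
}
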