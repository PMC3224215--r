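# Encoders: one-hot, BLOSUM62 and physico-chemical blocks, dimension
# arithmetic, and the training-set normalizer.

test_that("sparse encoding is one-hot over the documented 24-letter order", {
  v <- encode_sparse("A")
  expect_length(v, 24L)
  expect_equal(unname(v[1L]), 1)
  expect_equal(sum(v), 1)

  v9 <- encode_sparse("ACDEFGHIK")
  expect_length(v9, 216L)
  # per-residue sub-vectors each sum to exactly 1
  sums <- vapply(split(v9, rep(1:9, each = 24L)), sum, numeric(1L))
  expect_equal(unname(sums), rep(1, 9))
  # exactly L nonzero entries, all equal to 1
  expect_identical(sum(v9 != 0), 9L)
  expect_true(all(v9[v9 != 0] == 1))

  # placeholder letters are legal and hit the trailing components
  vb <- encode_sparse("B")
  expect_equal(unname(vb[22L]), 1)

  expect_error(encode_sparse("ACJ"), "position 3")
  expect_error(encode_sparse("ACJ"), "'J'")
  # deterministic
  expect_identical(encode_sparse("WYACK"), encode_sparse("WYACK"))
})

test_that("BLOSUM62 encoding uses the published NCBI rows", {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  ref <- e$BLOSUM62
  ord <- rownames(blosum62_matrix())
  expect_identical(
    unname(blosum62_matrix()),
    unname(ref[ord, ord])
  )
})

test_that("BLOSUM62 encoding places rows in sequence order", {
  v <- encode_blosum62("AC")
  expect_length(v, 48L)
  B <- blosum62_matrix()
  expect_equal(unname(v[1:24]), unname(B["A", ]))
  expect_equal(unname(v[25:48]), unname(B["C", ]))
  # diagonal component for residue A aligned with column A
  expect_equal(v[["blosum_p1_A"]], 4)

  expect_length(encode_blosum62("ACDEFGHI"), 192L)
  expect_identical(encode_blosum62("KLMNP"), encode_blosum62("KLMNP"))
  expect_error(encode_blosum62("AOA"), "position 2")
})

test_that("physico-chemical encoding concatenates table rows", {
  tab <- simulate_descriptor_table(3, seed = 4)
  v <- encode_physchem("AAA", tab)
  expect_length(v, 9L)
  expect_equal(unname(v[1:3]), unname(v[4:6]))
  expect_equal(unname(v[1:3]), unname(v[7:9]))
  expect_equal(unname(v[1:3]), unlist(tab[tab$aa == "A", -1L], use.names = FALSE))

  # arbitrary P and L give P * L features
  tab7 <- simulate_descriptor_table(7, seed = 5)
  expect_length(encode_physchem("ACDEF", tab7), 35L)

  # placeholders carry no property values
  expect_error(encode_physchem("AXA", tab), "position 2")
})

test_that("combined feature matrix obeys the (P + 48) * L dimension law", {
  tab3 <- simulate_descriptor_table(3, seed = 6)
  X <- build_feature_matrix(
    tibble::tibble(id = c("a", "b"), sequence = c("AC", "CA")), tab3
  )
  expect_identical(dim(X), c(2L, 102L)) # (3 + 48) * 2

  # blocks appear in the order phys | sparse | blosum with named columns
  info <- attr(X, "feature_info")
  expect_identical(unique(info$block), c("phys", "sparse", "blosum"))
  expect_identical(sum(info$block == "phys"), 6L)
  expect_identical(sum(info$block == "sparse"), 48L)

  for (case in list(c(L = 9, P = 5), c(L = 8, P = 12), c(L = 3, P = 1))) {
    tab <- simulate_descriptor_table(case[["P"]], seed = case[["P"]])
    peps <- simulate_peptides(3, case[["L"]], seed = 1)
    expect_identical(
      ncol(build_feature_matrix(peps, tab)),
      as.integer((case[["P"]] + 48) * case[["L"]])
    )
  }
})

test_that("normalizer drops zero-variance columns and standardizes the rest", {
  # hand-computed: population sd of (1,2,3) is sqrt(2/3)
  X <- cbind(a = c(0, 0, 0), b = c(1, 2, 3))
  norm <- fit_normalizer(X)
  expect_identical(norm$kept, 2L)
  expect_equal(norm$means, 2)
  expect_equal(norm$sds, sqrt(2 / 3))

  # no constant columns -> everything kept
  X2 <- matrix(rnorm(20), 5, 4)
  expect_identical(fit_normalizer(X2)$kept, 1:4)

  expect_error(fit_normalizer(X[1, , drop = FALSE]), "at least 2")
})

test_that("applying a normalizer standardizes train and maps test by train stats", {
  set.seed(8)
  X <- matrix(rnorm(60, mean = 3, sd = 2), 12, 5)
  colnames(X) <- letters[1:5]
  norm <- fit_normalizer(X)
  Z <- apply_normalizer(norm, X)
  expect_lt(max(abs(colMeans(Z))), 1e-9)
  expect_lt(max(abs(sqrt(colMeans(Z^2)) - 1)), 1e-9)

  # idempotence: refitting on the standardized matrix keeps all columns
  norm2 <- fit_normalizer(Z)
  expect_identical(norm2$kept, seq_len(ncol(Z)))
  expect_lt(max(abs(norm2$means)), 1e-9)
  expect_lt(max(abs(norm2$sds - 1)), 1e-9)

  # a test column constant at c maps to (c - mean) / sd, not re-dropped
  Xtest <- X
  Xtest[, 2L] <- 7
  Zt <- apply_normalizer(norm, Xtest)
  expect_equal(
    unname(Zt[, 2L]),
    rep((7 - norm$means[2L]) / norm$sds[2L], nrow(X))
  )

  expect_error(apply_normalizer(norm, X[, 1:3]), "columns")
})
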