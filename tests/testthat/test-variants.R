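test_that("apply_edit splices ref span for substitutions, deletions, insertions", {
  w <- reference_window("1", 1, "ACGTACGT")
  expect_equal(apply_edit(w, variant_record("1", 4, "T", "G")), "ACGGACGT")
  expect_equal(apply_edit(w, variant_record("1", 2, "CGT", "C")), "ACACGT")
  # string-splice oracle: paste the three pieces directly
  v <- variant_record("1", 3, "G", "GTT")
  expect_equal(apply_edit(w, v),
               paste0(substr("ACGTACGT", 1, 2), "GTT", substr("ACGTACGT", 4, 8)))
  expect_equal(nchar(apply_edit(w, v)), 8 - 1 + 3)
})

test_that("apply_edit rejects reference mismatches and out-of-window variants", {
  w <- reference_window("1", 10, "ACGTACGT")
  expect_error(apply_edit(w, variant_record("1", 12, "T", "A")), "mismatch")
  expect_error(apply_edit(w, variant_record("1", 5, "A", "T")), "outside")
  expect_error(apply_edit(w, variant_record("1", 16, "GTA", "G")), "outside")
})

test_that("normalization trims shared context and left-aligns in homopolymers", {
  w1 <- reference_window("1", 1, "AATCTGCCA")
  v1 <- normalize_variant(variant_record("1", 3, "TCTG", "TAAG"), w1)
  expect_equal(format_variant_id(v1), "1:4:CT:AA")

  w2 <- reference_window("1", 1, "AAGGGT")
  v2 <- normalize_variant(variant_record("1", 3, "GG", "G"), w2)
  expect_equal(format_variant_id(v2), "1:2:AG:A")
  # left-alignment preserves the edited product
  expect_equal(apply_edit(w2, v2), apply_edit(w2, variant_record("1", 3, "GG", "G")))

  # an already-canonical SNV is a fixed point
  v3 <- variant_record("1", 4, "G", "T")
  expect_equal(format_variant_id(normalize_variant(v3, w2)), "1:4:G:T")
})

test_that("normalization errors when left-shifting would leave the window", {
  w <- reference_window("1", 5, "GGGT")
  # pure deletion in a homopolymer starting at the window edge
  expect_error(normalize_variant(variant_record("1", 5, "GG", "G"), w),
               "context")
})

test_that("normalization is idempotent and product-preserving on random variants", {
  set.seed(101)
  for (i in 1:200) {
    case <- random_variant_case()
    # a deletion in a homopolymer running to the window edge legitimately
    # refuses to left-align; that error path has its own test above
    n1 <- tryCatch(normalize_variant(case$v, case$window),
                   error = function(e) NULL)
    if (is.null(n1)) next
    expect_equal(apply_edit(case$window, n1), apply_edit(case$window, case$v))
    n2 <- normalize_variant(n1, case$window)
    expect_identical(unclass(n1), unclass(n2))
  }
})

test_that("equivalence is edited-product identity and an equivalence relation", {
  w <- reference_window("1", 1, "ACGTA")
  v1 <- variant_record("1", 2, "CGT", "AAT")
  v2 <- variant_record("1", 2, "CG", "AA")
  expect_equal(apply_edit(w, v1), "AAATA")
  expect_true(variant_equivalent(v1, v2, w))
  expect_true(variant_equivalent(v1, v1, w))
  expect_false(variant_equivalent(variant_record("1", 4, "T", "G"),
                                  variant_record("1", 4, "T", "C"), w))

  # reflexive / symmetric / transitive over random variants on one window
  set.seed(7)
  win <- reference_window("1", 1, paste(sample(c("A", "C", "G", "T"), 30,
                                               replace = TRUE), collapse = ""))
  vs <- replicate(12, {
    pos <- sample(2:24, 1)
    ref <- substr(win$sequence, pos, pos + sample(0:2, 1))
    repeat {
      alt <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1),
                          replace = TRUE), collapse = "")
      if (alt != ref) break
    }
    variant_record("1", pos, ref, alt)
  }, simplify = FALSE)
  eq <- outer(seq_along(vs), seq_along(vs),
              Vectorize(function(i, j) variant_equivalent(vs[[i]], vs[[j]], win)))
  expect_true(all(diag(eq)))
  expect_identical(eq, t(eq))
  for (i in seq_along(vs)) for (j in seq_along(vs)) for (k in seq_along(vs))
    if (eq[i, j] && eq[j, k]) expect_true(eq[i, k])
})

test_that("unify collapses six representations of one delins into one class", {
  fix <- six_delins_representations()
  # derivation check: all six really produce the same product
  for (v in fix$variants)
    expect_equal(apply_edit(fix$window, v), fix$product)
  classes <- unify_variants(fix$variants, fix$window)
  expect_length(classes, 1L)
  expect_length(classes[[1]]$members, 6L)
  # the canonical representative reproduces the product too
  expect_equal(apply_edit(fix$window, classes[[1]]$canonical), fix$product)
})

test_that("unify keeps unrelated variants apart and partitions the input", {
  w <- reference_window("1", 1, "ACGTACGTAC")
  vs <- list(variant_record("1", 2, "C", "T"), variant_record("1", 7, "G", "A"))
  classes <- unify_variants(vs, w)
  expect_length(classes, 2L)
  expect_true(all(lengths(lapply(classes, `[[`, "members")) == 1L))
  expect_identical(unify_variants(list(), w), list())

  # partition property: class sizes sum to input size, each index once
  fix <- six_delins_representations()
  mixed <- c(fix$variants[1:3], vs <- list(
    variant_record("16", 2, substr(fix$window$sequence, 2, 2),
                   setdiff(c("A", "C", "G", "T"),
                           substr(fix$window$sequence, 2, 2))[1])))
  classes <- unify_variants(mixed, fix$window)
  idx <- sort(unlist(lapply(classes, `[[`, "indices")))
  expect_identical(idx, seq_along(mixed))
})
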