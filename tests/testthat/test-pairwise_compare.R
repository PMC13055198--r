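test_that("alignment identity behaves at the extremes", {
  expect_identical(global_alignment_identity("MKVQWERTA", "MKVQWERTA"), 100)
  expect_identical(global_alignment_identity("AAAA", "GGGG"), 0)
})

test_that("worked example matches the frozen independent result", {
  # score verified against Biostrings ends-free alignment
  aln <- global_alignment("HEAGAWGHEE", "PAWHEAE")
  expect_equal(aln$score, oracle_align_score("HEAGAWGHEE", "PAWHEAE"))
  expect_equal(aln$score, 15)
  expect_equal(aln$matches, 3L)
  expect_equal(aln$columns, 10L)
  expect_equal(aln$identity, 30)
})

test_that("alignment scores agree with Biostrings on random pairs", {
  set.seed(30)
  for (i in 1:40) {
    a <- random_aa_sequence(sample(3:40, 1))
    b <- random_aa_sequence(sample(3:40, 1))
    pen <- i %% 2 == 0
    aln <- global_alignment(a, b,
                            alignment_scoring(end_gaps_penalized = pen))
    expect_equal(aln$score, oracle_align_score(a, b, penalize_ends = pen),
                 tolerance = 1e-9)
    # aligned strings reproduce both inputs and are consistent columns
    expect_equal(gsub("-", "", aln$aligned_a, fixed = TRUE), a)
    expect_equal(gsub("-", "", aln$aligned_b, fixed = TRUE), b)
    expect_equal(nchar(aln$aligned_a), aln$columns)
    expect_equal(nchar(aln$aligned_b), aln$columns)
  }
})

test_that("identity is symmetric and bounded", {
  set.seed(31)
  for (i in 1:15) {
    a <- random_aa_sequence(sample(5:60, 1))
    b <- random_aa_sequence(sample(5:60, 1))
    ab <- global_alignment_identity(a, b)
    expect_equal(ab, global_alignment_identity(b, a), tolerance = 1e-9)
    expect_true(ab >= 0 && ab <= 100)
  }
})

test_that("non-standard gap penalties shift the optimum as expected", {
  # cheap gaps favor gapping the G out of AWGHE vs AWHE
  cheap <- alignment_scoring(gap_open = 1, gap_extend = 0.1)
  aln <- global_alignment("AWGHE", "AWHE", cheap)
  expect_equal(aln$score, oracle_align_score("AWGHE", "AWHE", 1, 0.1))
  expect_equal(aln$aligned_a, "AWGHE")
  expect_equal(aln$aligned_b, "AW-HE")
  expect_error(alignment_scoring(gap_open = -1), ">= 0")
})

test_that("residues missing from the substitution matrix are an error", {
  expect_error(global_alignment("MKU", "MKV"), "absent from the substitution")
})

test_that("pairwise matrices separate composition from primary sequence", {
  set.seed(32)
  s <- sequence_from_composition(qn_rich_target(), 100, seed = 33)
  sh <- shuffle_sequence(s)
  pm <- pairwise_matrix(c(orig = s, shuf = sh, same = s))
  # composition layer: shuffling never changes CI
  expect_identical(pm$ci["orig", "shuf"], 100)
  expect_identical(pm$ci["orig", "same"], 100)
  # primary-sequence layer: shuffling destroys identity, copying keeps it
  expect_lt(pm$identity["orig", "shuf"], 100)
  expect_identical(pm$identity["orig", "same"], 100)
  # symmetry and diagonals
  expect_equal(pm$ci, t(pm$ci))
  expect_equal(pm$identity, t(pm$identity))
  expect_equal(unname(diag(pm$ci)), rep(100, 3))
  expect_equal(unname(diag(pm$identity)), rep(100, 3))
  # ci layer equals the composition-core result exactly
  expect_identical(pm$ci["orig", "shuf"],
                   compositional_identity(composition(s), composition(sh)))
  expect_error(pairwise_matrix(c(a = "MKV", a = "MKV")), "duplicate")
  expect_error(pairwise_matrix(c(a = "MKV")), "at least 2")
})

test_that("matrix TSVs keep label order and 4-decimal values", {
  set.seed(34)
  seqs <- setNames(vapply(1:3, function(i) random_aa_sequence(40),
                          character(1)), c("b2", "a1", "c3"))
  pm <- pairwise_matrix(seqs)
  tf_ci <- withr::local_tempfile(fileext = ".tsv")
  tf_id <- withr::local_tempfile(fileext = ".tsv")
  write_pairwise_tsv(pm, tf_ci, tf_id)
  ci <- read.delim(tf_ci, check.names = FALSE)
  expect_equal(ci$id, c("b2", "a1", "c3"))        # input order, unsorted
  expect_equal(names(ci)[-1], c("b2", "a1", "c3"))
  expect_equal(as.numeric(ci[1, -1]), round(pm$ci[1, ], 4),
               ignore_attr = TRUE, tolerance = 1e-12)
  id <- read.delim(tf_id, check.names = FALSE)
  expect_equal(as.numeric(id[2, -1]), round(pm$identity[2, ], 4),
               ignore_attr = TRUE, tolerance = 1e-12)
})
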