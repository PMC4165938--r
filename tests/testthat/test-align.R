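test_that("self-alignment scores the matrix diagonal with identity 1", {
  bl <- blosum62_matrix
  p <- "ACDE"
  res <- smith_waterman(p, p)
  expect_equal(res$identity, 1)
  expect_equal(res$score, sum(diag(bl[strsplit(p, "")[[1]],
                                      strsplit(p, "")[[1]]])))
})

test_that("local alignment score is symmetric", {
  set.seed(41)
  for (k in 1:20) {
    a <- random_peptide(25)
    b <- random_peptide(30)
    expect_equal(smith_waterman(a, b)$score, smith_waterman(b, a)$score)
  }
})

test_that("local and global scores equal the brute-force DP on random 30-mers", {
  set.seed(42)
  for (k in 1:120) {
    a <- random_peptide(30)
    b <- random_peptide(30)
    expect_equal(smith_waterman(a, b)$score, ref_align_score(a, b, "local"))
    expect_equal(needleman_wunsch(a, b)$score, ref_align_score(a, b, "global"))
  }
})

test_that("global identity counts matches over alignment columns", {
  expect_equal(pairwise_identity("ACDE", "ACDF"), 0.75)
  expect_equal(pairwise_identity("ACDE", "ACDE"), 1)
  set.seed(43)
  for (k in 1:10) {
    a <- random_peptide(20)
    b <- random_peptide(24)
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
  expect_error(pairwise_identity("", "ACDE"), "empty")
})
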