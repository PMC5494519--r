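test_that("hand-checked alignments score as the substitution matrix dictates", {
  # three perfect A matches at BLOSUM62 A<->A = 4
  expect_identical(smith_waterman("AAA", "AAA")$score, 12L)
  # best local segment is the single W<->W pair (11); flanking K/A mismatch
  aln <- smith_waterman("KWK", "AWA")
  expect_identical(aln$score, 11L)
  expect_identical(c(aln$a_start, aln$a_end), c(2L, 2L))
  expect_identical(c(aln$b_start, aln$b_end), c(2L, 2L))
  expect_identical(smith_waterman("", "AAA")$score, 0L)
  expect_identical(smith_waterman("AAA", "")$score, 0L)
  expect_error(smith_waterman("AB1", "AAA"), "invalid residue")
})

test_that("the DP equals brute-force enumeration of all local alignments", {
  # low gap costs so gapped alignments are actually optimal sometimes
  ab <- c("A", "R", "N", "D")
  sub <- scoring_scheme()$matrix[ab, ab]
  scheme <- scoring_scheme(sub, gap_open = 2, gap_extend = 1)
  set.seed(14)
  lens <- c(rep(1:4, each = 8), rep(5:6, each = 3))
  for (la in sample(lens, 24)) {
    lb <- sample(lens, 1)
    a <- sample(ab, la, replace = TRUE)
    b <- sample(ab, lb, replace = TRUE)
    dp <- smith_waterman(a, b, scheme)$score
    bf <- sw_brute(match(a, ab), match(b, ab), sub, 2, 1)
    expect_identical(as.integer(dp), as.integer(bf))
  }
})

test_that("local alignment is symmetric for a symmetric matrix", {
  set.seed(15)
  aa <- rownames(scoring_scheme()$matrix)
  for (rep in 1:15) {
    a <- paste(sample(aa[1:20], 30, replace = TRUE), collapse = "")
    b <- paste(sample(aa[1:20], 25, replace = TRUE), collapse = "")
    expect_identical(smith_waterman(a, b)$score,
                     smith_waterman(b, a)$score)
  }
})

test_that("scores agree with an independent alignment engine", {
  set.seed(16)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (rep in 1:10) {
    a <- paste(sample(aa, 40, replace = TRUE), collapse = "")
    b <- paste(sample(aa, 45, replace = TRUE), collapse = "")
    ours <- smith_waterman(a, b)$score
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    expect_identical(as.integer(ours), as.integer(ref))
  }
})

test_that("the scramble null is degenerate for a length-1 sequence", {
  res <- scramble_test("WKDW", "W", n_each = 5, seed = 3)
  expect_identical(length(res$null_scores), 10L)
  # scrambles of both sequences include identity permutations often enough
  # that null scores repeat; for length-1 B they are all equal
  expect_identical(length(unique(res$null_scores[1:5])), 1L)
  expect_true(res$exceed_fraction >= 0 && res$exceed_fraction <= 1)
})

test_that("a self-alignment dominates every scramble", {
  set.seed(17)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  s <- paste(sample(aa, 50, replace = TRUE), collapse = "")
  res <- scramble_test(s, s, n_each = 100, seed = 5)
  expect_identical(res$exceed_fraction, 0)
  expect_identical(length(res$null_scores), 200L)
  expect_true(all(res$null_scores < res$observed$score))
})

test_that("the exceedance fraction is the fraction of null scores >= observed", {
  set.seed(18)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  a <- paste(sample(aa, 60, replace = TRUE), collapse = "")
  b <- paste(sample(aa, 55, replace = TRUE), collapse = "")
  res <- scramble_test(a, b, n_each = 30, seed = 9)
  expect_equal(res$exceed_fraction,
               mean(res$null_scores >= res$observed$score))
  res2 <- scramble_test(a, b, n_each = 30, seed = 9)
  expect_identical(res$null_scores, res2$null_scores)   # seeded
})

test_that("FASTA input round-trips through the aligner", {
  tmp <- tempfile(fileext = ".fasta")
  writeLines(c(">p1", "MKWVTFISLLLLFSSAYS", ">p2", "MKWVTAISLLLLFSSAYS"),
             tmp)
  seqs <- read_protein_fasta(tmp)
  expect_identical(names(seqs), c("p1", "p2"))
  aln <- smith_waterman(seqs[[1]], seqs[[2]])
  expect_gt(aln$score, 50)
})
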