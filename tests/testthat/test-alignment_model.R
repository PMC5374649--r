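test_that("alignment pairs enforce the column invariants", {
  a <- alignment_pair("ATG---", "---ATG")
  expect_identical(a$L, 6L)
  expect_error(alignment_pair("ATG", "ATGATG"), "different lengths")
  expect_error(alignment_pair("AT-", "AT-"), "gaps in both rows")
  expect_error(alignment_pair("ATGA--", "ATGATG"), "multiple of 3")
  expect_error(alignment_pair("ATN---", "---ATG"), "only A, C, G, T")
})

test_that("non-gap letter counts use 1-based inclusive columns", {
  expect_identical(nongap_count("ACCAT--GTAG", 4, 8), 3L)
  expect_identical(nongap_count("A----T", 2, 5), 0L)   # all-gap span
  expect_identical(nongap_count("ACGTAC", 2, 5), 4L)   # gap-free span
  expect_identical(nongap_count("ACCAT--GTAG", 1, 11), 9L)
  expect_error(nongap_count("ACGT", 0, 2), "out of range")
  expect_error(nongap_count("ACGT", 3, 5), "out of range")
})

test_that("codon classification reproduces the reference alignment sets", {
  fx <- reference_fixture()
  cls <- fx$classification
  ex <- fx$expected
  expect_identical(sort(cls$a$im), ex$im)
  expect_identical(sort(cls$b$im), ex$im)   # IM sets agree across directions
  expect_identical(sort(cls$a$fsext), ex$fsext_a)
  expect_identical(sort(cls$a$indel), ex$indel_a)
  expect_identical(sort(cls$a$mfs), ex$mfs_a)
  expect_identical(sort(cls$b$fsext), ex$fsext_b)
  expect_identical(sort(cls$b$indel), ex$indel_b)
  expect_identical(sort(cls$b$mfs), ex$mfs_b)
})

test_that("codon classification handles elementary alignments", {
  cls <- classify_codons(alignment_pair("ATG", "ATG"))
  expect_identical(cls$a$im, 3L)
  expect_identical(cls$b$im, 3L)
  expect_length(c(cls$a$fsext, cls$a$indel, cls$a$fsinit, cls$a$mfs,
                  cls$b$fsext, cls$b$indel, cls$b$fsinit, cls$b$mfs), 0L)

  cls <- classify_codons(alignment_pair("ATG---", "---ATG"))
  expect_identical(cls$a$indel, 3L)
  expect_identical(cls$b$indel, 6L)
  expect_length(c(cls$a$im, cls$a$fsext, cls$a$fsinit,
                  cls$b$im, cls$b$fsext, cls$b$fsinit), 0L)

  # per sequence the four classes partition the codons
  set.seed(3)
  space <- enumerate_alignments(random_cds(6), random_cds(6))
  for (aln in sample(space, 20)) {
    cls <- classify_codons(aln)
    for (d in c("a", "b"))
      expect_identical(length(cls[[d]]$im) + length(cls[[d]]$fsext) +
                         length(cls[[d]]$indel) + length(cls[[d]]$fsinit), 2L)
  }
})

test_that("direct scorer matches a term-by-term evaluation on the fixture", {
  fx <- reference_fixture()
  sets <- fx$expected
  for (sc in c(oracle_schemes(),
               list(scoring_scheme(gap_mode = "affine")))) {
    direct <- score_alignment(fx$alignment, sc)
    byterms <- score_by_terms(fx$alignment$a_gapped, fx$alignment$b_gapped,
                              sets, sc)
    if (sc$gap_mode == "affine")  # one indel run per sequence in the fixture
      byterms <- byterms + 2 * sc$gap_open_cost
    expect_equal(direct, byterms)
  }
})

test_that("direct scorer agrees with hand-computable cases", {
  lin <- scoring_scheme(gap_mode = "linear")
  expect_identical(score_alignment(alignment_pair("ATG", "ATG"), lin), 5)
  expect_identical(score_alignment(alignment_pair("ATG---", "---ATG"), lin),
                   -2)
  aff <- scoring_scheme(gap_mode = "affine")
  expect_identical(score_alignment(alignment_pair("ATG---", "---ATG"), aff),
                   -2 + 2 * aff$gap_open_cost)
  # affine charges one opening per maximal indel-codon run
  aln <- alignment_pair("ATGATG------", "------ATGATG")
  expect_identical(score_alignment(aln, aff),
                   -4 + 2 * aff$gap_open_cost)
})

test_that("alignment score is symmetric and linear in fs_extend_cost", {
  set.seed(19)
  fe_on <- scoring_scheme(gap_mode = "linear", fs_extend_cost = -1)
  fe_off <- scoring_scheme(gap_mode = "linear", fs_extend_cost = 0)
  space <- enumerate_alignments(random_cds(6), random_cds(9))
  for (aln in sample(space, 25)) {
    swapped <- alignment_pair(aln$b_gapped, aln$a_gapped)
    expect_equal(score_alignment(aln, fe_on),
                 score_alignment(swapped, fe_on))
    # removing the extension penalty shifts the score by the FSext count
    cls <- classify_codons(aln)
    nfsext <- length(cls$a$fsext) + length(cls$b$fsext)
    expect_equal(score_alignment(aln, fe_off) - score_alignment(aln, fe_on),
                 nfsext)
  }
})

test_that("gap-free identical alignments are all-IM with diagonal score", {
  sc <- scoring_scheme()
  for (seed in 1:5) {
    s <- random_cds(24, seed = seed)
    aln <- alignment_pair(s$nucleotides, s$nucleotides)
    cls <- classify_codons(aln)
    expect_identical(length(cls$a$im), 8L)
    expect_identical(length(cls$b$im), 8L)
    diag_sum <- sum(vapply(1:8, function(k)
      aa_score(sc, substr(s$nucleotides, 3 * k - 2, 3 * k),
               substr(s$nucleotides, 3 * k - 2, 3 * k)), 0))
    expect_equal(score_alignment(aln, sc), diag_sum)
  }
})

test_that("column accounting: gapped + match + mismatch columns = L", {
  set.seed(23)
  space <- enumerate_alignments(random_cds(6), random_cds(6))
  for (aln in sample(space, 20)) {
    ca <- strsplit(aln$a_gapped, "")[[1]]
    cb <- strsplit(aln$b_gapped, "")[[1]]
    gapped <- sum(ca == "-" | cb == "-")
    match <- sum(ca != "-" & cb != "-" & ca == cb)
    mismatch <- sum(ca != "-" & cb != "-" & ca != cb)
    expect_identical(gapped + match + mismatch, aln$L)
  }
})
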