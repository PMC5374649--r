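test_that("the six criteria reproduce the worked reference values", {
  fx <- reference_fixture()
  cr <- fx$criteria
  expect_identical(cr$identity_nt, 28L)
  expect_identical(cr$identity_aa, 14L)
  expect_identical(cr$gap_init, 7L)
  expect_identical(cr$gap_length, 15L)
  expect_identical(cr$fs_init, 3L)
  expect_identical(cr$fs_length, 11L)
  expect_identical(cr$gap_init_columns, c(4L, 16L, 22L, 27L, 31L, 36L, 44L))
  expect_identical(cr$fs_segment_starts, c(18L, 28L, 39L))
})

test_that("frameshift segments are maximal FSext-covered column runs", {
  fx <- reference_fixture()
  seg <- fs_segments(fx$classification, fx$alignment$L)
  expect_equal(unname(seg),
               cbind(c(18L, 28L, 39L), c(21L, 30L, 42L)),
               ignore_attr = TRUE)
  expect_identical(sum(seg[, "end"] - seg[, "start"] + 1L), 11L)

  # no FSext codons, no segments
  cls <- classify_codons(alignment_pair("ATGATG", "ATGATG"))
  expect_identical(nrow(fs_segments(cls, 6L)), 0L)
})

test_that("criteria on elementary alignments", {
  # identical gap-free pair of k codons: (3k, 2k, 0, 0, 0, 0)
  for (k in c(1L, 4L, 7L)) {
    s <- random_cds(3L * k, seed = k)
    cr <- compute_criteria(alignment_pair(s$nucleotides, s$nucleotides))
    expect_identical(unlist(cr[1:6], use.names = FALSE),
                     c(3L * k, 2L * k, 0L, 0L, 0L, 0L))
  }
  # facing indels: the deletion-to-insertion switch opens a second gap run
  cr <- compute_criteria(alignment_pair("ATG---", "---ATG"))
  expect_identical(unlist(cr[1:6], use.names = FALSE),
                   c(0L, 0L, 2L, 6L, 0L, 0L))
})

test_that("criteria invariants hold across the alignment space", {
  set.seed(47)
  space <- enumerate_alignments(random_cds(6), random_cds(6))
  for (aln in sample(space, 30)) {
    cls <- classify_codons(aln)
    cr <- compute_criteria(aln, cls)
    ca <- strsplit(aln$a_gapped, "")[[1]]
    cb <- strsplit(aln$b_gapped, "")[[1]]
    mismatch <- sum(ca != "-" & cb != "-" & ca != cb)
    expect_identical(cr$identity_nt + mismatch + cr$gap_length, aln$L)
    seg <- fs_segments(cls, aln$L)
    expect_identical(cr$fs_init, nrow(seg))
    expect_identical(cr$fs_length,
                     if (nrow(seg)) sum(seg[, "end"] - seg[, "start"] + 1L)
                     else 0L)
    if (!length(cls$a$fsext) && !length(cls$b$fsext)) {
      expect_identical(cr$fs_init, 0L)
      expect_identical(cr$fs_length, 0L)
    }
    expect_lte(cr$fs_init, cr$fs_length)
  }
})

test_that("normalized scores divide by the alignment length", {
  expect_equal(normalized_score(-24, 48), -0.5)
  expect_equal(normalized_score(5, 3), 5 / 3)
  expect_error(normalized_score(1, 0), "positive")
  # invariance under swapping the pair
  sc <- scoring_scheme(gap_mode = "linear")
  a <- random_cds(12, seed = 5); b <- random_cds(9, seed = 6)
  f1 <- cds_align(a, b, sc); f2 <- cds_align(b, a, sc)
  expect_equal(f1$normalized, f2$normalized)
})
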