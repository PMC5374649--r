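test_that("CDS validation enforces length and alphabet, warns on partials", {
  x <- suppressWarnings(cds("x", "ATGGAATAA"))
  expect_s3_class(x, "cds")
  expect_identical(x$codon_count, 3L)
  expect_identical(x$n, 9L)

  expect_error(cds("x", "ATGGA"), "length 5 not a multiple of 3")
  expect_error(cds("x", "ATGNAATAA"), "position 4")
  expect_error(cds("x", "ATGNAATAA"), "'N'")

  # lowercase input is uppercased before validation
  expect_identical(cds("x", "atggaataa")$nucleotides, "ATGGAATAA")
  # missing start / stop codons warn but do not fail
  expect_warning(cds("y", "GGGTAA"), "start codon")
  expect_warning(cds("y", "ATGGGG"), "stop codon")
  expect_silent(cds("y", "ATGTAA"))
  expect_silent(cds("empty", ""))
})

test_that("translation uses the standard code and preserves codon count", {
  expect_identical(translate_cds("ATG"), "M")
  expect_identical(translate_cds("TAA"), "*")
  expect_identical(translate_cds(""), "")
  expect_identical(translate_cds("ATGGAATAA"), "ME*")
  for (len in c(0L, 3L, 30L, 99L)) {
    s <- random_cds(len, seed = len + 1L, avoid_stops = FALSE)
    expect_identical(nchar(translate_cds(s)), len %/% 3L)
  }
})

test_that("amino-acid codon scoring is symmetric and silent-mutation blind", {
  sc <- scoring_scheme()
  expect_identical(aa_score(sc, "ATG", "ATG"), 5)  # BLOSUM62 M/M diagonal
  # silent mutation scores as identity (both CTG and CTA encode leucine)
  expect_identical(aa_score(sc, "CTG", "CTA"), aa_score(sc, "CTG", "CTG"))
  # stop pairings
  expect_identical(aa_score(sc, "ATG", "TAA"), sc$stop_cost)
  expect_identical(aa_score(sc, "TAA", "TGA"), sc$stop_match)

  nts <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(nts, nts, nts), 1, paste, collapse = "")
  # exhaustive symmetry over all 64 x 64 codon pairs
  for (c1 in codons) for (c2 in codons)
    if (aa_score(sc, c1, c2) != aa_score(sc, c2, c1))
      fail(sprintf("aa_score not symmetric for %s / %s", c1, c2))
  succeed()
  # synonymous codon pairs score as self-identity, exhaustively
  aa <- vapply(codons, function(cd) translate_cds(cd), "")
  for (a1 in split(codons, aa)) for (c1 in a1) for (c2 in a1)
    if (aa_score(sc, c1, c2) != aa_score(sc, c1, c1))
      fail(sprintf("synonymous pair %s / %s breaks identity", c1, c2))
  succeed()
})

test_that("nucleotide scoring is +1/-1 by default, symmetric, gap-free", {
  sc <- scoring_scheme()
  expect_identical(an_score(sc, "A", "A"), 1)
  expect_identical(an_score(sc, "A", "G"), -1)
  nts <- c("A", "C", "G", "T")
  for (x in nts) for (y in nts)
    expect_identical(an_score(sc, x, y), an_score(sc, y, x))
  expect_error(an_score(sc, "-", "A"), "nucleotides only")
})

test_that("scheme construction validates penalties and symmetry", {
  expect_error(scoring_scheme(gap_cost = 1), "<= 0")
  expect_error(scoring_scheme(fs_open_cost = 5), "<= 0")
  asym <- blosum62()
  asym["A", "R"] <- 99
  expect_error(scoring_scheme(s_aa = asym), "symmetric")
  # fs_extend_cost = 0 is the allowed boundary (no extension penalty)
  expect_silent(scoring_scheme(fs_extend_cost = 0))
})

test_that("NCBI-format matrix files round-trip through the parser", {
  m <- blosum62()
  path <- tempfile(fileext = ".txt")
  writeLines(c("# test matrix",
               paste(" ", paste(colnames(m), collapse = " ")),
               vapply(rownames(m), function(r)
                 paste(r, paste(m[r, ], collapse = " ")), "")),
             path)
  parsed <- read_score_matrix(path)
  expect_identical(dimnames(parsed), dimnames(m))
  expect_equal(unname(parsed), unname(m))
  expect_true("*" %in% rownames(parsed))
  sc <- scoring_scheme(s_aa = parsed)
  expect_identical(aa_score(sc, "ATG", "ATG"), 5)
})
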