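# shared scheme set used by the oracle-equivalence and property tests:
# linear mode with varying frameshift penalties
oracle_schemes <- function() {
  list(
    scoring_scheme(gap_mode = "linear", fs_extend_cost = -1,
                   fs_open_cost = -30),
    scoring_scheme(gap_mode = "linear", fs_extend_cost = 0,
                   fs_open_cost = -30),
    scoring_scheme(gap_mode = "linear", fs_extend_cost = -0.5,
                   fs_open_cost = -10),
    scoring_scheme(gap_mode = "linear", fs_extend_cost = -1,
                   fs_open_cost = -10),
    scoring_scheme(gap_mode = "linear", fs_extend_cost = 0,
                   fs_open_cost = -10)
  )
}

# independent term-by-term evaluation of the alignment score from a known
# classification: used as the oracle for the direct scorer (shares no code
# with score_alignment)
score_by_terms <- function(arow, brow, sets, scheme) {
  ca <- strsplit(arow, "")[[1]]
  cb <- strsplit(brow, "")[[1]]
  trip <- function(chars, e) paste(chars[(e - 2):e], collapse = "")
  total <- 0
  for (e in sets$im)
    total <- total + aa_score(scheme, trip(ca, e), trip(cb, e))
  for (e in sets$fsext_a)
    total <- total + aa_score(scheme, trip(ca, e), trip(cb, e)) / 2 +
      scheme$fs_extend_cost
  for (e in sets$fsext_b)
    total <- total + aa_score(scheme, trip(cb, e), trip(ca, e)) / 2 +
      scheme$fs_extend_cost
  total <- total + length(sets$indel_a) * scheme$gap_cost +
    length(sets$indel_b) * scheme$gap_cost
  nfsinit_a <- nchar(gsub("-", "", arow)) / 3 - length(sets$im) -
    length(sets$fsext_a) - length(sets$indel_a)
  nfsinit_b <- nchar(gsub("-", "", brow)) / 3 - length(sets$im) -
    length(sets$fsext_b) - length(sets$indel_b)
  total <- total + (nfsinit_a + nfsinit_b) * scheme$fs_open_cost
  for (k in sets$mfs_a)
    total <- total + an_score(scheme, ca[k], cb[k]) / 2
  for (k in sets$mfs_b)
    total <- total + an_score(scheme, cb[k], ca[k]) / 2
  total
}
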