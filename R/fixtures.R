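# Deterministic synthetic data: a fully worked 48-column reference alignment
# whose codon classification and criteria are known exactly, and a generator
# for frameshift-inducing sequence pairs (single-nucleotide deletion plus an
# appended tail).

#' Reference 48-column alignment with known classification and criteria
#'
#' A deterministic alignment of a 13-codon sequence against a 14-codon
#' sequence exhibiting every codon class: in-frame matches (ending at columns
#' 3, 9, 12, 15, 26, 48), frameshift extensions in both directions, one codon
#' indel per sequence, and frameshift-initiation codons with matched
#' nucleotides.  Nucleotide mismatches occur exactly at columns 9, 12, 15,
#' 42 and 45; the mismatches at 9 and 12 are synonymous, the in-frame pair
#' ending at 15 is AAG/AAT (K vs N) and the frameshift-extension codon AAT
#' ending at 42 faces the triplet AAG.  The constructor verifies its own
#' classification and criteria against the expected sets and fails loudly if
#' they do not reproduce.
#'
#' @return A list with \code{alignment}, \code{classification},
#'   \code{criteria}, and \code{expected} (the reference sets the fixture is
#'   checked against).
#' @export
reference_fixture <- function() {
  arow <- paste0("ATG", "GAA", "CTG", "GGA", "AAG", "--",
                 "CTGG", "AC", "GAT", "GACA", "---", "GA", "---",
                 "GAAG", "C", "-", "A", "TGC")
  brow <- paste0("ATG", "---", "CTA", "GGC", "AAT", "CA",
                 "CTGG", "--", "GAT", "-ACA", "TTC", "GA", "CTT",
                 "GAAT", "C", "A", "G", "TGC")
  aln <- alignment_pair(arow, brow, ids = c("A", "B"))
  stopifnot(aln$L == 48L)
  expected <- list(
    im = c(3L, 9L, 12L, 15L, 26L, 48L),
    fsext_a = c(20L, 41L), indel_a = 6L,
    mfs_a = c(21L, 28L, 29L, 30L, 34L, 35L, 42L, 43L, 45L),
    fsext_b = c(21L, 30L, 42L), indel_b = 33L,
    mfs_b = c(18L, 34L, 35L, 39L, 43L, 45L),
    criteria = c(identity_nt = 28L, identity_aa = 14L, gap_init = 7L,
                 gap_length = 15L, fs_init = 3L, fs_length = 11L),
    gap_init_columns = c(4L, 16L, 22L, 27L, 31L, 36L, 44L),
    fs_segment_starts = c(18L, 28L, 39L))
  cls <- classify_codons(aln)
  ok <- identical(sort(cls$a$im), expected$im) &&
    identical(sort(cls$b$im), expected$im) &&
    identical(sort(cls$a$fsext), expected$fsext_a) &&
    identical(sort(cls$a$indel), expected$indel_a) &&
    identical(sort(cls$a$mfs), expected$mfs_a) &&
    identical(sort(cls$b$fsext), expected$fsext_b) &&
    identical(sort(cls$b$indel), expected$indel_b) &&
    identical(sort(cls$b$mfs), expected$mfs_b)
  if (!ok) stop("internal error: fixture classification does not reproduce ",
                "the reference sets")
  crit <- compute_criteria(aln, cls)
  got <- vapply(names(expected$criteria), function(nm)
    as.integer(crit[[nm]]), 0L)
  if (!identical(unname(got), unname(expected$criteria)))
    stop("internal error: fixture criteria do not reproduce the reference ",
         "values")
  list(alignment = aln, classification = cls, criteria = crit,
       expected = expected)
}

#' Random coding sequence
#'
#' Uniform random nucleotides; with \code{avoid_stops} the three stop codons
#' are excluded at in-frame positions (each codon is redrawn until it is not
#' a stop).
#'
#' @param length nucleotide length, a multiple of 3.
#' @param seed optional integer seed (local to this call).
#' @param avoid_stops exclude in-frame TAA/TAG/TGA (default TRUE).
#' @param id sequence label.
#' @return A \code{\link{cds}} object.
#' @export
random_cds <- function(length, seed = NULL, avoid_stops = TRUE, id = "rnd") {
  if (length %% 3L != 0L || length < 0L)
    stop("length must be a non-negative multiple of 3")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  nts <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  draw_codon <- function() {
    repeat {
      cod <- paste(sample(nts, 3L, replace = TRUE), collapse = "")
      if (!avoid_stops || !cod %in% stops) return(cod)
    }
  }
  s <- paste(vapply(seq_len(length %/% 3L), function(k) draw_codon(), ""),
             collapse = "")
  cds(id, s, warn_partial = FALSE)
}

#' Generate a frameshift-inducing CDS pair
#'
#' Emulates the construction of a frameshifted homolog: a random stop-free
#' base CDS, from which a derived CDS is obtained by deleting one nucleotide
#' at a given position and appending a random tail, trimmed so the total
#' length is a multiple of 3.  With \code{base_length = 45},
#' \code{tail_length = 16} the derived sequence has length 60; deleting late
#' (position 30) yields a short frameshifted suffix, deleting early
#' (position 15) a long one.  The base and the tail depend only on the seed,
#' not on the deletion position, so derived sequences for different deletion
#' positions are directly comparable.
#'
#' @param base_length base CDS length (multiple of 3, default 45).
#' @param deletion_position 1-based nucleotide index to delete (default 30).
#' @param tail_length nucleotides appended (default 16).
#' @param seed integer seed.
#' @return A list with \code{base} and \code{derived} \code{\link{cds}}
#'   objects.
#' @export
generate_fs_pair <- function(base_length = 45, deletion_position = 30,
                             tail_length = 16, seed = 1L) {
  if (base_length %% 3L != 0L) stop("base_length must be a multiple of 3")
  if (deletion_position < 1L || deletion_position > base_length)
    stop("deletion_position out of range 1..", base_length)
  total <- base_length - 1L + tail_length
  keep <- total - total %% 3L
  base <- random_cds(base_length, seed = seed, avoid_stops = TRUE,
                     id = "base")
  tail_seed <- seed + 1000003L
  tail <- random_cds(3L * ceiling(tail_length / 3), seed = tail_seed,
                     avoid_stops = FALSE, id = "tail")$nucleotides
  s <- paste0(substr(base$nucleotides, 1L, deletion_position - 1L),
              substr(base$nucleotides, deletion_position + 1L, base_length),
              substr(tail, 1L, tail_length))
  s <- substr(s, 1L, keep)
  derived <- cds(sprintf("derived_del%d", deletion_position), s,
                 warn_partial = FALSE)
  list(base = base, derived = derived)
}
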