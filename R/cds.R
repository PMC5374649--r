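#' Validate a coding sequence
#'
#' A coding sequence (CDS) is a DNA string over \code{A,C,G,T} whose length is
#' a multiple of 3; its codons are the triplets ending at positions 3, 6, ...
#' Input is uppercased before validation.  A sequence that does not begin with
#' the start codon \code{ATG} or does not end with a stop codon
#' (\code{TAA}/\code{TAG}/\code{TGA}) triggers a warning, not an error: many
#' useful inputs (sub-sequences, synthetic fixtures) are not complete
#' biological CDS.
#'
#' @param id character label for the sequence.
#' @param raw character string of nucleotides (lowercase accepted).
#' @param warn_partial warn when start/stop codons are absent (default TRUE).
#' @return An object of class \code{"cds"}: a list with elements \code{id},
#'   \code{nucleotides}, \code{n} (nucleotide length) and \code{codon_count}.
#' @examples
#' x <- cds("x", "ATGGAATAA")
#' x$codon_count  # 3
#' @export
cds <- function(id, raw, warn_partial = TRUE) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(raw), length(raw) == 1L)
  s <- toupper(raw)
  n <- nchar(s)
  if (n %% 3L != 0L)
    stop(sprintf("sequence '%s': length %d not a multiple of 3", id, n))
  if (n > 0L) {
    bad <- regexpr("[^ACGT]", s)
    if (bad > 0L)
      stop(sprintf("sequence '%s': invalid symbol '%s' at position %d",
                   id, substr(s, bad, bad), bad))
    if (warn_partial) {
      if (substr(s, 1L, 3L) != "ATG")
        warning(sprintf("sequence '%s' does not begin with a start codon", id))
      if (!substr(s, n - 2L, n) %in% c("TAA", "TAG", "TGA"))
        warning(sprintf("sequence '%s' does not end with a stop codon", id))
    }
  }
  structure(list(id = id, nucleotides = s, n = n, codon_count = n %/% 3L),
            class = "cds")
}

#' @export
print.cds <- function(x, ...) {
  cat(sprintf("CDS '%s': %d nt (%d codons)\n", x$id, x$n, x$codon_count))
  if (x$n > 0L) {
    shown <- if (x$n > 60L) paste0(substr(x$nucleotides, 1L, 57L), "...")
             else x$nucleotides
    cat(" ", shown, "\n")
  }
  invisible(x)
}

as_cds <- function(x, id = "seq") {
  if (inherits(x, "cds")) x else cds(id, x, warn_partial = FALSE)
}

# light sequence wrapper for operations defined on arbitrary DNA (no
# multiple-of-3 requirement): enumeration of the alignment space
.as_seq <- function(x, id = "seq") {
  if (inherits(x, "cds")) return(x)
  s <- toupper(x)
  if (nchar(s) > 0L && grepl("[^ACGT]", s))
    stop("sequence contains symbols outside A, C, G, T")
  list(id = id, nucleotides = s, n = nchar(s))
}

#' Translate a coding sequence
#'
#' Codon-by-codon translation under the standard genetic code, with \code{*}
#' for stop codons.
#'
#' @param x a \code{\link{cds}} object or a nucleotide string whose length is
#'   a multiple of 3.
#' @return A character string of amino acids, one per codon.
#' @examples
#' translate_cds("ATGGAATAA")  # "ME*"
#' @export
translate_cds <- function(x) {
  x <- as_cds(x)
  if (x$n == 0L) return("")
  paste(aa_of_triplets(x$nucleotides), collapse = "")
}

# amino acids of all consecutive codons of a gap-free string
aa_of_triplets <- function(s) {
  n <- nchar(s)
  starts <- seq.int(1L, n - 2L, by = 3L)
  unname(.codon_table[substring(s, starts, starts + 2L)])
}

# standard genetic code as a named vector, '*' for stops
.codon_table <- {
  gc <- Biostrings::GENETIC_CODE
  structure(as.character(gc), names = names(gc))
}
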