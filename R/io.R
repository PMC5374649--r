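# FASTA input/output and the all-pairs driver.

#' Read coding sequences from a FASTA file
#'
#' Sequences are uppercased and validated (\code{\link{cds}}).  Under
#' \code{strict = TRUE} an invalid record aborts with an error naming it;
#' otherwise invalid records are reported with a warning and skipped.
#'
#' @param path FASTA file.
#' @param strict fail on the first invalid record (default TRUE).
#' @return A named list of \code{\link{cds}} objects in file order.
#' @export
read_cds_fasta <- function(path, strict = TRUE) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  out <- list()
  for (k in seq_along(set)) {
    id <- names(set)[k]
    res <- tryCatch(cds(id, as.character(set[[k]]), warn_partial = FALSE),
                    error = identity)
    if (inherits(res, "error")) {
      if (strict) stop("invalid CDS record: ", conditionMessage(res))
      warning("skipping invalid CDS record: ", conditionMessage(res))
    } else out[[id]] <- res
  }
  if (!length(out)) stop("no valid CDS records in ", path)
  out
}

#' Write an alignment as aligned FASTA
#'
#' Two records of equal length with \code{-} gap symbols.
#'
#' @param aln an \code{\link{alignment_pair}} (or a \code{cds_align} result).
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_alignment_fasta <- function(aln, path) {
  if (inherits(aln, "cds_align")) aln <- aln$alignment
  set <- Biostrings::BStringSet(c(aln$a_gapped, aln$b_gapped))
  names(set) <- aln$ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read an aligned FASTA file as an alignment pair
#'
#' @param path aligned FASTA with exactly two records of equal length.
#' @return An \code{\link{alignment_pair}}.
#' @export
read_alignment_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) != 2L)
    stop("expected exactly 2 records in ", path, ", found ", length(set))
  alignment_pair(as.character(set[[1L]]), as.character(set[[2L]]),
                 ids = names(set))
}

#' Align all pairs of a sequence collection
#'
#' Runs the aligner over every unordered pair (or a given pair list) and
#' tabulates scores and composition criteria.  Optionally writes one aligned
#' FASTA per pair, a TSV report and a square normalized-similarity matrix.
#' Output is deterministic: pairs are processed in input order.
#'
#' @param seqs named list of \code{\link{cds}} (e.g. from
#'   \code{\link{read_cds_fasta}}).
#' @param scheme a \code{\link{scoring_scheme}}.
#' @param pairs optional 2-column matrix/data.frame of sequence ids; default
#'   all N(N-1)/2 unordered pairs.
#' @param out_dir optional output directory for per-pair aligned FASTA files,
#'   \code{report.tsv} and \code{similarity.tsv}.
#' @return A data.frame with one row per pair: ids, raw and normalized score,
#'   the six criteria and the frameshift-segment start columns.
#' @export
run_pairwise <- function(seqs, scheme = scoring_scheme(), pairs = NULL,
                         out_dir = NULL) {
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("sequences must be named")
  if (is.null(pairs)) {
    pairs <- if (length(ids) >= 2L) t(utils::combn(ids, 2L))
             else matrix(character(0), 0L, 2L)
  } else {
    pairs <- as.matrix(pairs)
    if (ncol(pairs) != 2L) stop("pairs must have two columns")
    missing <- setdiff(unique(c(pairs)), ids)
    if (length(missing))
      stop("unknown sequence id(s): ", paste(missing, collapse = ", "))
  }
  rows <- vector("list", nrow(pairs))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  for (k in seq_len(nrow(pairs))) {
    ia <- pairs[k, 1L]; ib <- pairs[k, 2L]
    fit <- cds_align(seqs[[ia]], seqs[[ib]], scheme)
    cr <- fit$criteria
    rows[[k]] <- data.frame(
      id_a = ia, id_b = ib, score = fit$score, normalized = fit$normalized,
      identity_nt = cr$identity_nt, identity_aa = cr$identity_aa,
      gap_init = cr$gap_init, gap_length = cr$gap_length,
      fs_init = cr$fs_init, fs_length = cr$fs_length,
      fs_segment_starts = paste(cr$fs_segment_starts, collapse = ","),
      stringsAsFactors = FALSE)
    if (!is.null(out_dir))
      write_alignment_fasta(fit$alignment,
                            file.path(out_dir, sprintf("%s__%s.fasta", ia, ib)))
  }
  report <- if (length(rows)) do.call(rbind, rows) else data.frame(
    id_a = character(0), id_b = character(0), score = numeric(0),
    normalized = numeric(0), identity_nt = integer(0),
    identity_aa = integer(0), gap_init = integer(0), gap_length = integer(0),
    fs_init = integer(0), fs_length = integer(0),
    fs_segment_starts = character(0), stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    utils::write.table(report, file.path(out_dir, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sim <- matrix(NA_real_, length(ids), length(ids),
                  dimnames = list(ids, ids))
    for (k in seq_len(nrow(report))) {
      sim[report$id_a[k], report$id_b[k]] <- report$normalized[k]
      sim[report$id_b[k], report$id_a[k]] <- report$normalized[k]
    }
    utils::write.table(sim, file.path(out_dir, "similarity.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  report
}

#' Pair counts of a dataset manifest
#'
#' Unordered pair counts N(N-1)/2 per family and their total.
#'
#' @param counts integer vector of per-family sequence counts (optionally
#'   named).
#' @return A list with \code{per_family} and \code{total}.
#' @examples
#' pair_manifest(c(14, 10, 10, 33, 33, 44, 44, 19, 30, 24))$total  # 4011
#' @export
pair_manifest <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  per <- counts * (counts - 1) / 2
  list(per_family = per, total = sum(per))
}
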