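#' Globally align a read against an amplicon reference
#'
#' Needleman-Wunsch global alignment with affine gap penalties
#' (defaults: match +2, mismatch -3, gap open -5, gap extend -1) via
#' `Biostrings::pairwiseAlignment()`. Reads whose alignment identity
#' (matches / alignment columns) falls below `min_identity` are flagged
#' unaligned rather than raising an error, and are excluded from all
#' quantification denominators downstream.
#'
#' @param read DNA string (the merged or single read).
#' @param reference An [build_reference()] object.
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Gap penalties (negative).
#' @param min_identity Minimum identity for the read to count as aligned.
#' @param read_id Optional identifier carried through to results.
#' @return A `read_alignment` object: list with `read_id`, `aligned`,
#'   `identity`, `ref_calls` (character vector over reference positions:
#'   the read base, `"-"` where deleted, `NA` where the alignment did not
#'   cover), and `insertions` (tibble `after_ref_pos`, `length`, `seq`).
#' @export
align_read <- function(read, reference,
                       match = 2, mismatch = -3,
                       gap_open = -5, gap_extend = -1,
                       min_identity = 0.6,
                       read_id = NA_character_) {
  stopifnot(inherits(reference, "amplicon_reference"))
  read <- assert_dna(read)
  if (nchar(read) == 0L) abort("`read` must be non-empty.")
  refseq <- reference$full_sequence
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = read, subject = refseq, type = "global",
    substitutionMatrix = mat,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend))
  alignment_from_strings(
    as.character(Biostrings::alignedPattern(aln)),
    as.character(Biostrings::alignedSubject(aln)),
    nchar(refseq), read_id, min_identity)
}

# walk a gapped pattern/subject pair into per-reference-position calls
alignment_from_strings <- function(pat_str, sub_str, n_ref,
                                   read_id, min_identity) {
  pat <- strsplit(pat_str, "")[[1]]
  sub <- strsplit(sub_str, "")[[1]]
  ref_calls <- rep(NA_character_, n_ref)
  ins <- list()
  ref_pos <- 0L
  i <- 1L
  n_col <- length(pat)
  while (i <= n_col) {
    if (sub[i] != "-") {
      ref_pos <- ref_pos + 1L
      ref_calls[ref_pos] <- if (pat[i] == "-") "-" else pat[i]
      i <- i + 1L
    } else {
      # insertion run relative to the reference, anchored after ref_pos
      j <- i
      while (j <= n_col && sub[j] == "-") j <- j + 1L
      ins[[length(ins) + 1L]] <- tibble(
        after_ref_pos = ref_pos,
        length = j - i,
        seq = paste(pat[i:(j - 1L)], collapse = ""))
      i <- j
    }
  }
  # canonicalize gap placement: left-align each deletion run (equivalent
  # alignments place a gap anywhere within a repeat context; the leftmost
  # placement is the standard normal form)
  refseq <- sub[sub != "-"]
  repeat {
    moved <- FALSE
    p <- 1L
    while (p <= n_ref) {
      if (!is.na(ref_calls[p]) && ref_calls[p] == "-") {
        q <- p
        while (q < n_ref && !is.na(ref_calls[q + 1L]) &&
               ref_calls[q + 1L] == "-") q <- q + 1L
        while (p > 1L && !is.na(ref_calls[p - 1L]) &&
               ref_calls[p - 1L] != "-" && refseq[p - 1L] == refseq[q]) {
          ref_calls[q] <- ref_calls[p - 1L]
          ref_calls[p - 1L] <- "-"
          p <- p - 1L
          q <- q - 1L
          moved <- TRUE
        }
        p <- q + 1L
      } else {
        p <- p + 1L
      }
    }
    if (!moved) break
  }
  matches <- sum(pat == sub & pat != "-")
  identity <- matches / n_col
  structure(list(
    read_id = read_id,
    aligned = identity >= min_identity,
    identity = identity,
    ref_calls = ref_calls,
    insertions = if (length(ins)) bind_rows(ins) else
      tibble(after_ref_pos = integer(), length = integer(), seq = character())
  ), class = "read_alignment")
}

#' Align a batch of reads
#'
#' @param reads Character vector of read sequences (names used as ids when
#'   present).
#' @inheritParams align_read
#' @return List of `read_alignment` objects.
#' @export
align_reads <- function(reads, reference,
                        match = 2, mismatch = -3,
                        gap_open = -5, gap_extend = -1,
                        min_identity = 0.6) {
  stopifnot(inherits(reference, "amplicon_reference"))
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%05d", seq_along(reads))
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(toupper(unname(reads))),
    subject = reference$full_sequence, type = "global",
    substitutionMatrix = mat,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend))
  pats <- as.character(Biostrings::alignedPattern(aln))
  subs <- as.character(Biostrings::alignedSubject(aln))
  n_ref <- nchar(reference$full_sequence)
  map(seq_along(reads), function(i) {
    alignment_from_strings(pats[i], subs[i], n_ref, ids[i], min_identity)
  })
}

#' @export
print.read_alignment <- function(x, ...) {
  cat("<read_alignment> ", x$read_id,
      if (x$aligned) " aligned" else " UNALIGNED",
      sprintf(" (identity %.3f); deletions %d nt, insertions %d\n",
              x$identity, sum(x$ref_calls == "-", na.rm = TRUE),
              nrow(x$insertions)), sep = "")
  invisible(x)
}

# does this alignment carry an insertion or deletion overlapping the
# half-open interval [lo, hi)? (1-based inclusive interval passed as lo..hi)
alignment_has_indel_overlap <- function(alignment, lo, hi) {
  del_pos <- which(alignment$ref_calls == "-")
  if (any(del_pos >= lo & del_pos <= hi)) return(TRUE)
  ins <- alignment$insertions
  if (nrow(ins) > 0L) {
    # an insertion after ref position p sits between p and p+1; it disrupts
    # the region only when that junction is interior to lo..hi
    if (any(ins$after_ref_pos >= lo & ins$after_ref_pos <= hi - 1L)) return(TRUE)
  }
  FALSE
}
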