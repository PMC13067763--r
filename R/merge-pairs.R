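#' Merge a paired-end read by ungapped overlap
#'
#' Reverse-complements read 2 and scans every ungapped overlap between the
#' 3' end of read 1 and the 5' end of the reverse-complemented read 2,
#' keeping the overlap with the most matching bases among those at least
#' `min_overlap` long with a mismatch fraction at most `max_mismatch_frac`
#' (ties go to the longer overlap). Disagreements inside the overlap are
#' resolved toward the base with the higher Phred quality, ties to read 1.
#' Amplicons here are fixed-length, so no indel is allowed across the
#' junction; pairs with no acceptable overlap are flagged unmerged.
#'
#' @param read1,read2 DNA strings (read 2 in sequencer orientation).
#' @param qual1,qual2 Optional Phred+33 quality strings, same lengths.
#' @param min_overlap Minimum overlap length (default 15).
#' @param max_mismatch_frac Maximum mismatch fraction in the overlap
#'   (default 0.1).
#' @return List: `merged` (logical), `sequence` (NA when unmerged),
#'   `overlap`, `mismatches`.
#' @examples
#' s <- "ACGTACGTACGTACGTACGTACGT"
#' merge_pair(substr(s, 1, 20),
#'            as.character(Biostrings::reverseComplement(
#'              Biostrings::DNAString(substr(s, 5, 24)))))
#' @export
merge_pair <- function(read1, read2, qual1 = NULL, qual2 = NULL,
                       min_overlap = 15L, max_mismatch_frac = 0.1) {
  read1 <- assert_dna(read1)
  read2 <- assert_dna(read2)
  if (nchar(read1) == 0L || nchar(read2) == 0L) {
    abort("reads must be non-empty.")
  }
  r1 <- strsplit(read1, "")[[1]]
  r2 <- strsplit(revcomp(read2), "")[[1]]
  q1 <- if (is.null(qual1)) rep(30L, length(r1)) else
    as.integer(charToRaw(qual1)) - 33L
  q2 <- if (is.null(qual2)) rep(30L, length(r2)) else
    rev(as.integer(charToRaw(qual2)) - 33L)
  if (length(q1) != length(r1) || length(q2) != length(r2)) {
    abort("quality strings must match read lengths.")
  }
  n1 <- length(r1); n2 <- length(r2)
  best <- NULL
  for (L in seq_len(min(n1, n2))) {
    a <- r1[(n1 - L + 1L):n1]
    b <- r2[1:L]
    mm <- sum(a != b)
    if (L < min_overlap || mm / L > max_mismatch_frac) next
    score <- L - mm
    if (is.null(best) || score > best$score ||
        (score == best$score && L > best$L)) {
      best <- list(L = L, mm = mm, score = score)
    }
  }
  if (is.null(best)) {
    return(list(merged = FALSE, sequence = NA_character_,
                overlap = 0L, mismatches = NA_integer_))
  }
  L <- best$L
  ov1 <- (n1 - L + 1L):n1
  ov2 <- 1:L
  consensus <- r1[ov1]
  disagree <- which(r1[ov1] != r2[ov2])
  for (k in disagree) {
    if (q2[ov2[k]] > q1[ov1[k]]) consensus[k] <- r2[ov2[k]]
  }
  seq <- paste(c(head(r1, n1 - L), consensus, tail(r2, n2 - L)),
               collapse = "")
  list(merged = TRUE, sequence = seq, overlap = L, mismatches = best$mm)
}

#' Merge a batch of read pairs
#'
#' @param reads1,reads2 Character vectors of paired reads.
#' @param quals1,quals2 Optional quality string vectors.
#' @param ... Passed to [merge_pair()].
#' @return Tibble: `read`, `merged`, `sequence`, `overlap`; unmerged pairs
#'   keep `NA` sequences (drop them before counting).
#' @export
merge_pairs <- function(reads1, reads2, quals1 = NULL, quals2 = NULL, ...) {
  stopifnot(length(reads1) == length(reads2))
  out <- map(seq_along(reads1), function(i) {
    m <- merge_pair(reads1[i], reads2[i],
                    qual1 = if (is.null(quals1)) NULL else quals1[i],
                    qual2 = if (is.null(quals2)) NULL else quals2[i], ...)
    tibble(read = i, merged = m$merged, sequence = m$sequence,
           overlap = m$overlap)
  })
  bind_rows(out)
}
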