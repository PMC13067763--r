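#' Simulate edited amplicon reads with a ground-truth ledger
#'
#' Draws reads from an amplicon reference under a simple generative model of
#' base-editing outcomes: each read either receives one indel (insertion or
#' deletion, probability `indel_prob`; length 1 + geometric(`indel_geom_p`);
#' position uniform over the protospacer-plus-PAM region) or receives
#' independent per-cytosine conversions (C-to-T with the per-position
#' probability, otherwise C-to-A/G split equally with probability
#' `c_to_other_prob`), then uniform sequencing errors at `error_rate` per
#' base. Every true event is recorded in a ledger, so downstream
#' quantification can be checked exactly (at zero sequencing error) or
#' within binomial sampling error. Output is a deterministic function of
#' the seed.
#'
#' @param reference A [build_reference()] object.
#' @param n_reads Number of read pairs (>= 1).
#' @param c_to_t_prob Either a single probability applied to every
#'   protospacer cytosine, or a named vector keyed by PAM-relative position
#'   (positions absent from the vector get 0).
#' @param c_to_other_prob Probability of C-to-A/G conversion at the same
#'   cytosines (split equally between A and G).
#' @param indel_prob Per-read probability of one indel overlapping the
#'   protospacer/PAM region.
#' @param indel_geom_p Geometric parameter for indel length (length is
#'   1 + rgeom(p); default 0.5).
#' @param error_rate Per-base uniform sequencing error probability.
#' @param read_length Length of each mate; pairs are drawn from the two ends
#'   of the (possibly indel-modified) amplicon and overlap in the middle.
#' @param seed Integer seed; same spec and seed give identical output.
#' @return List: `reads` (tibble `read_id`, `full_seq`, `read1`, `read2`,
#'   `qual1`, `qual2`), `ledger` (tibble `read_id`, `indel`, `indel_type`,
#'   `indel_len`, `indel_pos`, `c_to_t_positions` and `c_to_other_positions`
#'   list columns of PAM-relative positions, `n_seq_errors`), and
#'   `reference`.
#' @export
simulate_amplicon_reads <- function(reference,
                                    n_reads = 2000L,
                                    c_to_t_prob = 0.3,
                                    c_to_other_prob = 0,
                                    indel_prob = 0,
                                    indel_geom_p = 0.5,
                                    error_rate = 0,
                                    read_length = 60L,
                                    seed = NULL) {
  stopifnot(inherits(reference, "amplicon_reference"))
  if (n_reads < 1L) abort("`n_reads` must be >= 1.")
  probs <- c(c_to_t_prob, c_to_other_prob, indel_prob, error_rate)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1].")
  refseq <- strsplit(reference$full_sequence, "")[[1]]
  n_ref <- length(refseq)
  pam_rel <- ref_to_pam_relative(reference, seq_len(n_ref))
  c_coords <- which(refseq == "C" & !is.na(pam_rel))
  c_positions <- pam_rel[c_coords]
  p_ct <- if (!is.null(names(c_to_t_prob))) {
    p <- unname(c_to_t_prob[as.character(c_positions)])
    p[is.na(p)] <- 0
    p
  } else rep(c_to_t_prob, length(c_coords))
  region <- reference$protospacer_interval[1]:reference$pam_interval[2]

  with_seed(seed, {
    reads <- vector("list", n_reads)
    ledger <- vector("list", n_reads)
    for (k in seq_len(n_reads)) {
      s <- refseq
      is_indel <- runif(1) < indel_prob
      indel_type <- NA_character_; indel_len <- NA_integer_
      indel_pos <- NA_integer_
      ct_hits <- integer(0); co_hits <- integer(0)
      if (is_indel) {
        indel_type <- if (runif(1) < 0.5) "deletion" else "insertion"
        indel_len <- 1L + rgeom(1, indel_geom_p)
        if (indel_type == "deletion") {
          # reject positions whose left-aligned gap placement would slide
          # out of the protospacer/PAM region (repeat-context ambiguity)
          repeat {
            indel_pos <- sample(region, 1L)
            trunc_len <- min(indel_len, n_ref - indel_pos + 1L)
            left <- indel_pos
            while (left > 1L && s[left - 1L] == s[left + trunc_len - 1L]) {
              left <- left - 1L
            }
            if (left >= region[1]) break
          }
          del <- indel_pos:min(indel_pos + indel_len - 1L, n_ref)
          s <- s[-del]
        } else {
          # interior junctions only, and the flanking insert bases are kept
          # different from the neighbouring reference bases so the gap
          # placement is alignment-unambiguous
          indel_pos <- sample(region[-length(region)], 1L)
          insert <- sample(DNA_BASES, indel_len, replace = TRUE)
          if (indel_len == 1L) {
            insert[1] <- sample(
              setdiff(DNA_BASES, s[indel_pos + c(0L, 1L)]), 1L)
          } else {
            insert[1] <- sample(setdiff(DNA_BASES, s[indel_pos + 1L]), 1L)
            insert[indel_len] <- sample(setdiff(DNA_BASES, s[indel_pos]), 1L)
          }
          s <- append(s, insert, after = indel_pos)
        }
      } else if (length(c_coords) > 0L) {
        u <- runif(length(c_coords))
        hit_t <- u < p_ct
        hit_o <- !hit_t & u < p_ct + c_to_other_prob
        s[c_coords[hit_t]] <- "T"
        if (any(hit_o)) {
          s[c_coords[hit_o]] <- sample(c("A", "G"), sum(hit_o), replace = TRUE)
        }
        ct_hits <- sort(c_positions[hit_t])
        co_hits <- sort(c_positions[hit_o])
      }
      n_err <- 0L
      if (error_rate > 0) {
        err <- which(runif(length(s)) < error_rate)
        n_err <- length(err)
        for (e in err) {
          s[e] <- sample(setdiff(DNA_BASES, s[e]), 1L)
        }
      }
      full <- paste(s, collapse = "")
      L <- min(read_length, nchar(full))
      r1 <- substr(full, 1L, L)
      r2 <- revcomp(substr(full, nchar(full) - L + 1L, nchar(full)))
      reads[[k]] <- tibble(
        read_id = sprintf("sim%05d", k), full_seq = full,
        read1 = r1, read2 = r2,
        qual1 = strrep("I", L), qual2 = strrep("I", L))
      ledger[[k]] <- tibble(
        read_id = sprintf("sim%05d", k),
        indel = is_indel, indel_type = indel_type,
        indel_len = indel_len, indel_pos = indel_pos,
        c_to_t_positions = list(ct_hits),
        c_to_other_positions = list(co_hits),
        n_seq_errors = n_err)
    }
    list(reads = bind_rows(reads), ledger = bind_rows(ledger),
         reference = reference)
  })
}
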