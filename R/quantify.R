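#' Quantify base-editing outcomes from aligned reads
#'
#' Implements the read-accounting conventions of amplicon base-editing
#' analysis: the indel frequency is the percentage of aligned reads carrying
#' an insertion or deletion overlapping the protospacer-plus-PAM region,
#' over all aligned reads. Reads with such indels are excluded from
#' substitution numerators and denominators (their base calls at deleted
#' positions are undefined and mixing them in would double-count outcomes).
#' Substitution outcomes are reported per PAM-relative protospacer position
#' and aggregated into the window classes: (i) C-to-T within the analysis
#' window, (ii) C-to-T outside it (amplicon level), (iii) other
#' substitutions within the window. C-to-D means C to any of A/G/T, so the
#' window C-to-T percentage can never exceed the C-to-D percentage.
#'
#' @param alignments List of [align_read()] results.
#' @param reference The [build_reference()] object they were aligned to.
#' @param window Inclusive PAM-relative window `c(low, high)`; defaults to
#'   the reference's `analysis_window`.
#' @return A `quant_result` object: list with `summary` (one-row tibble:
#'   `n_reads`, `n_reads_aligned`, `n_indel_reads`, `indel_pct`,
#'   `c_to_t_window_pct`, `c_to_d_window_pct`, `out_of_window_c_to_t_pct`,
#'   `other_subs_window_pct`) and `positions` (per PAM-relative position
#'   1-20: `ref_base`, `depth`, counts and rates of C-to-T/A/G).
#' @export
quantify_edits <- function(alignments, reference, window = NULL) {
  stopifnot(inherits(reference, "amplicon_reference"))
  if (length(alignments) == 0L) abort("no alignments supplied.")
  if (is.null(window)) window <- reference$analysis_window
  refseq <- strsplit(reference$full_sequence, "")[[1]]
  ps <- reference$protospacer_interval
  region_lo <- ps[1]
  region_hi <- reference$pam_interval[2]

  aligned <- purrr::keep(alignments, "aligned")
  n_reads <- length(alignments)
  n_aligned <- length(aligned)
  if (n_aligned == 0L) abort("zero aligned reads; nothing to quantify.")

  has_indel <- map_lgl(aligned, alignment_has_indel_overlap,
                       lo = region_lo, hi = region_hi)
  n_indel <- sum(has_indel)
  subs_reads <- aligned[!has_indel]
  n_subs <- length(subs_reads)

  # PAM-relative coordinates of every full-sequence position (NA outside)
  pam_rel <- ref_to_pam_relative(reference, seq_along(refseq))
  in_window_coord <- !is.na(pam_rel) & pam_rel >= window[1] & pam_rel <= window[2]

  # per-position bookkeeping over the protospacer
  pos_tbl <- tibble(
    position = 1:20,
    ref_base = refseq[match(1:20, pam_rel)],
    depth = 0L, n_c_to_t = 0L, n_c_to_a = 0L, n_c_to_g = 0L
  )
  read_flags <- map(subs_reads, function(a) {
    calls <- a$ref_calls
    covered <- !is.na(calls) & calls != "-"
    is_sub <- covered & calls != refseq
    c_pos <- refseq == "C"
    c_to_t <- is_sub & c_pos & calls == "T"
    c_to_a <- is_sub & c_pos & calls == "A"
    c_to_g <- is_sub & c_pos & calls == "G"
    list(covered = covered, is_sub = is_sub,
         c_to_t = c_to_t, c_to_a = c_to_a, c_to_g = c_to_g)
  })
  if (n_subs > 0L) {
    for (p in 1:20) {
      coord <- match(p, pam_rel)
      pos_tbl$depth[p] <- sum(map_lgl(read_flags, ~ .x$covered[coord]))
      if (!is.na(pos_tbl$ref_base[p]) && pos_tbl$ref_base[p] == "C") {
        pos_tbl$n_c_to_t[p] <- sum(map_lgl(read_flags, ~ .x$c_to_t[coord]))
        pos_tbl$n_c_to_a[p] <- sum(map_lgl(read_flags, ~ .x$c_to_a[coord]))
        pos_tbl$n_c_to_g[p] <- sum(map_lgl(read_flags, ~ .x$c_to_g[coord]))
      }
    }
  }
  pos_tbl <- pos_tbl %>%
    mutate(
      rate_c_to_t = ifelse(.data$depth > 0, .data$n_c_to_t / .data$depth, 0),
      rate_c_to_a = ifelse(.data$depth > 0, .data$n_c_to_a / .data$depth, 0),
      rate_c_to_g = ifelse(.data$depth > 0, .data$n_c_to_g / .data$depth, 0)
    )

  # read-level window classes over substitution-eligible reads
  pct <- function(k) if (n_subs > 0L) 100 * k / n_subs else 0
  read_class <- map(read_flags, function(fl) {
    sub_window <- fl$is_sub & in_window_coord
    c_to_d <- fl$c_to_t | fl$c_to_a | fl$c_to_g
    list(
      ctt_in = any(fl$c_to_t & in_window_coord),
      ctd_in = any(c_to_d & in_window_coord),
      ctt_out = any(fl$c_to_t & !in_window_coord),
      other_in = any(sub_window & !(fl$c_to_t & in_window_coord))
    )
  })
  summary <- tibble(
    n_reads = n_reads,
    n_reads_aligned = n_aligned,
    n_indel_reads = n_indel,
    indel_pct = 100 * n_indel / n_aligned,
    c_to_t_window_pct = pct(sum(map_lgl(read_class, "ctt_in"))),
    c_to_d_window_pct = pct(sum(map_lgl(read_class, "ctd_in"))),
    out_of_window_c_to_t_pct = pct(sum(map_lgl(read_class, "ctt_out"))),
    other_subs_window_pct = pct(sum(map_lgl(read_class, "other_in")))
  )
  structure(list(summary = summary, positions = pos_tbl,
                 window = as.integer(window)),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<quant_result> %d reads (%d aligned): indel %.2f%%, window C-to-T %.2f%%, C-to-D %.2f%% (window %d-%d)\n",
    s$n_reads, s$n_reads_aligned, s$indel_pct, s$c_to_t_window_pct,
    s$c_to_d_window_pct, x$window[1], x$window[2]))
  invisible(x)
}

#' Infer the empirical editing window from a positional profile
#'
#' Finds the maximal contiguous run of PAM-relative positions whose C-to-T
#' rate is at least `threshold_fraction` of the maximal positional rate.
#' Between equal-length runs the PAM-proximal one (smaller positions) wins.
#'
#' @param positions The `positions` tibble of a [quantify_edits()] result
#'   (or any tibble with `position` and `rate_c_to_t`).
#' @param threshold_fraction Fraction of the peak rate a position must reach
#'   to belong to the window (default 0.3).
#' @return Inclusive integer pair `c(low, high)`.
#' @export
infer_editing_window <- function(positions, threshold_fraction = 0.3) {
  if (inherits(positions, "quant_result")) positions <- positions$positions
  positions <- as_tibble(positions)
  if (!all(c("position", "rate_c_to_t") %in% names(positions))) {
    abort("`positions` needs columns position and rate_c_to_t.")
  }
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    abort("`threshold_fraction` must lie in (0, 1).")
  }
  positions <- arrange(positions, .data$position)
  r <- positions$rate_c_to_t
  if (all(r == 0)) abort("no editing detected: all positional C-to-T rates are zero.")
  qualifies <- r >= threshold_fraction * max(r)
  runs <- rle(qualifies)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  lens <- runs$lengths[keep]
  best <- keep[which(lens == max(lens))]
  best <- best[which.min(starts[best])] # PAM-proximal tie-break
  c(positions$position[starts[best]], positions$position[ends[best]])
}
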