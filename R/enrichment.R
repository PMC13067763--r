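#' Count variant sequences per selection round
#'
#' Exact, sequence-keyed cumulative counting of reconstructed reads per
#' round of iterative selection.
#'
#' @param reads_by_round Named list (one element per round, names like
#'   `"1"`, `"2"`, ...) of character vectors of reconstructed sequences, or
#'   a tibble with columns `round` and `sequence`.
#' @return A tibble of class `round_count_table`: `variant`, `round`
#'   (integer), `count`, covering every variant-round combination (zero
#'   counts included).
#' @export
count_variants <- function(reads_by_round) {
  if (is.data.frame(reads_by_round)) {
    df <- as_tibble(reads_by_round)
    if (!all(c("round", "sequence") %in% names(df))) {
      abort("tibble input needs columns round, sequence.")
    }
  } else {
    if (is.null(names(reads_by_round))) {
      names(reads_by_round) <- seq_along(reads_by_round)
    }
    df <- imap(reads_by_round, ~ tibble(round = .y, sequence = .x)) %>%
      bind_rows()
  }
  df$round <- as.integer(df$round)
  counts <- df %>%
    group_by(.data$round, variant = .data$sequence) %>%
    summarise(count = dplyr::n(), .groups = "drop")
  out <- tidyr::complete(counts, .data$variant, .data$round,
                         fill = list(count = 0L)) %>%
    arrange(.data$variant, .data$round)
  structure(out, class = c("round_count_table", class(out)))
}

#' Fold enrichment of variants across selection rounds
#'
#' Converts per-round counts to relative abundances (frequencies) and
#' computes, for each variant, the ratio of its final-round frequency to its
#' first-round frequency. Variants absent from the first round would have
#' infinite fold change, so the denominator frequency is floored at
#' `pseudocount / round-1 total` (default half a read). With
#' `use_frequencies = FALSE` the ratio is taken on raw counts instead
#' (denominator floored at `pseudocount` reads).
#'
#' @param counts A [count_variants()] table, or any tibble with `variant`,
#'   `round`, `count`.
#' @param pseudocount Reads floored into the round-1 denominator
#'   (default 0.5).
#' @param from,to Rounds compared (defaults: first and last present).
#' @param use_frequencies Compare frequencies (default) or raw counts.
#' @return Tibble of class `enrichment_records`: `variant`, `count_from`,
#'   `count_to`, `freq_from`, `freq_to`, `fold`, sorted by descending fold.
#' @export
fold_enrichment <- function(counts, pseudocount = 0.5,
                            from = NULL, to = NULL,
                            use_frequencies = TRUE) {
  counts <- as_tibble(counts)
  if (nrow(counts) == 0L) {
    return(structure(tibble(variant = character(), count_from = integer(),
                            count_to = integer(), freq_from = numeric(),
                            freq_to = numeric(), fold = numeric()),
                     class = c("enrichment_records", class(tibble()))))
  }
  rounds <- sort(unique(counts$round))
  if (length(rounds) < 2L) abort("need at least two rounds.")
  if (is.null(from)) from <- rounds[1]
  if (is.null(to)) to <- rounds[length(rounds)]
  totals <- counts %>%
    group_by(.data$round) %>%
    summarise(total = sum(.data$count), .groups = "drop")
  tot_from <- totals$total[totals$round == from]
  tot_to <- totals$total[totals$round == to]
  if (tot_from == 0L || tot_to == 0L) abort("a compared round has zero reads.")
  wide <- counts %>%
    filter(.data$round %in% c(from, to)) %>%
    tidyr::pivot_wider(names_from = "round", values_from = "count",
                       values_fill = 0L)
  cf <- wide[[as.character(from)]]
  ct <- wide[[as.character(to)]]
  if (use_frequencies) {
    ff <- cf / tot_from
    ft <- ct / tot_to
    fold <- ft / pmax(ff, pseudocount / tot_from)
  } else {
    ff <- cf / tot_from
    ft <- ct / tot_to
    fold <- ct / pmax(cf, pseudocount)
  }
  out <- tibble(variant = wide$variant,
                count_from = cf, count_to = ct,
                freq_from = cf / tot_from, freq_to = ct / tot_to,
                fold = fold) %>%
    arrange(desc(.data$fold), .data$variant)
  structure(out, class = c("enrichment_records", class(out)),
            from = from, to = to, pseudocount = pseudocount)
}

#' Select enrichment hits
#'
#' Hits are variants whose abundance increased more than `threshold`-fold
#' between the compared rounds; the comparison is strict (`>`), so a variant
#' at exactly the threshold is not a hit.
#'
#' @param records A [fold_enrichment()] table.
#' @param threshold Fold-change cutoff (default 1000).
#' @return Tibble of hits sorted by descending fold (possibly empty).
#' @export
select_hits <- function(records, threshold = 1000) {
  records <- as_tibble(records)
  if (nrow(records) == 0L) return(records)
  records %>%
    filter(.data$fold > threshold) %>%
    arrange(desc(.data$fold), .data$variant)
}

#' Fold change relative to a reference value
#'
#' Simple improvement ratio used when comparing a variant's mean activity,
#' indel rate or BEPI against a reference editor (e.g. engineered variant
#' vs wild type).
#'
#' @param value,reference Positive numerics (vectorized).
#' @return `value / reference`.
#' @examples
#' fold_change(28.2, 2.38) # ~11.8-fold activity gain
#' @export
fold_change <- function(value, reference) {
  if (any(reference <= 0)) abort("`reference` must be positive.")
  value / reference
}

#' Enumerate a combinatorial mutant library
#'
#' Cartesian product of the allowed residues at each mutated site. Variant
#' names concatenate one letter per site in position order (e.g. `RQVK`
#' style for a four-site library).
#'
#' @param sites Named list: names are ORF positions, values are character
#'   vectors of allowed one-letter residues. With `include_wt = TRUE` the
#'   first residue of each site is taken as wild type and is guaranteed to
#'   be present (the all-wild-type combination is then in the library).
#' @param include_wt Keep/insert the wild-type residue at every site.
#' @param sep Separator between per-site letters in the variant name.
#' @return Tibble of class `variant_library`: `name` plus one column per
#'   site (`p<position>`); `nrow` is the product of the per-site set sizes.
#' @examples
#' lib <- enumerate_combinatorial_library(sites_4mix())
#' nrow(lib) # 90
#' @export
enumerate_combinatorial_library <- function(sites, include_wt = TRUE,
                                            sep = "") {
  if (length(sites) == 0L) abort("`sites` must be non-empty.")
  pos <- as.integer(names(sites))
  if (any(is.na(pos))) abort("`sites` names must be integer positions.")
  if (anyDuplicated(pos)) abort("duplicate site positions.")
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  sets <- map(sites, function(res) {
    res <- toupper(res)
    if (!all(res %in% aa20)) {
      abort(sprintf("non-standard residues: %s",
                    paste(setdiff(res, aa20), collapse = ", ")))
    }
    unique(res)
  })
  ord <- order(pos)
  pos <- pos[ord]; sets <- sets[ord]
  grid <- rev(expand.grid(rev(sets), stringsAsFactors = FALSE))
  names(grid) <- paste0("p", pos)
  out <- as_tibble(grid)
  out$name <- apply(grid, 1, paste, collapse = sep)
  out <- select(out, "name", dplyr::everything())
  structure(out, class = c("variant_library", class(out)),
            positions = pos,
            wild_type = if (include_wt) paste(map_chr(sets, 1), collapse = sep)
            else NA_character_)
}

#' Four-site combinatorial library site specification
#'
#' The high-performing substitutions recovered for the four DNA-binding
#' positions, wild type first: R14 (R/D/W), Q17 (Q/P), V33 (V/F/H/W/Y),
#' K39 (K/A/I). The full Cartesian library has 3 x 2 x 5 x 3 = 90 members
#' including the all-wild-type sequence.
#'
#' @return Named list suitable for [enumerate_combinatorial_library()].
#' @export
sites_4mix <- function() {
  list(`14` = c("R", "D", "W"),
       `17` = c("Q", "P"),
       `33` = c("V", "F", "H", "W", "Y"),
       `39` = c("K", "A", "I"))
}
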