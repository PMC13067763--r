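#' Per-variant survival under the three selection axes
#'
#' Combines the three selection pressures of the bacterial screen into a
#' single survival probability per round:
#' `activity * exp(-dsb_hazard * copies) * viability`. `activity` is the
#' probability of rescuing the defective resistance-gene start codon,
#' `dsb_hazard` the per-repeat-copy lethality from double-strand breaks at
#' the repeat target (`copies` genomic copies), and `viability` the
#' probability of tolerating continuous expression. This quantitative form
#' is a modeling choice for exercising the counting and enrichment stages;
#' the biology specifies only the qualitative logic.
#'
#' @param activity,viability Probabilities in \[0, 1\].
#' @param dsb_hazard Non-negative per-copy hazard.
#' @param copies Repeat copy number (2, 7 or 12 in the reference system).
#' @return Survival probabilities in \[0, 1\].
#' @export
selection_survival <- function(activity, dsb_hazard = 0, copies = 2L,
                               viability = 1) {
  if (any(activity < 0 | activity > 1) || any(viability < 0 | viability > 1)) {
    abort("`activity` and `viability` must lie in [0, 1].")
  }
  if (any(dsb_hazard < 0)) abort("`dsb_hazard` must be >= 0.")
  activity * exp(-dsb_hazard * copies) * viability
}

#' Simulate multi-round selection counts
#'
#' Iterative selection with a per-round bottleneck: round 1 samples the
#' input library multinomially at its initial frequencies; each later round
#' samples proportionally to (previous frequency x survival probability).
#' Deterministic given the seed.
#'
#' @param library Tibble with columns `variant` and `survival` (per-round
#'   survival probability, e.g. from [selection_survival()]); an optional
#'   `freq0` column sets initial frequencies (default uniform).
#' @param rounds Number of rounds (default 4).
#' @param bottleneck Reads/colonies sampled per round (default 1e5).
#' @param seed Integer seed.
#' @return List: `counts` (a `round_count_table`: `variant`, `round`,
#'   `count`) and `truth` (the library tibble with normalized `freq0`).
#' @export
simulate_screen_rounds <- function(library, rounds = 4L,
                                   bottleneck = 1e5, seed = NULL) {
  library <- as_tibble(library)
  if (!all(c("variant", "survival") %in% names(library)) ||
      nrow(library) == 0L) {
    abort("`library` needs rows with columns variant, survival.")
  }
  if (anyDuplicated(library$variant)) abort("variant names must be unique.")
  if (all(library$survival <= 0)) abort("library extinct: all survival zero.")
  if (rounds < 2L) abort("`rounds` must be >= 2.")
  freq0 <- if ("freq0" %in% names(library)) library$freq0 else
    rep(1, nrow(library))
  freq0 <- freq0 / sum(freq0)
  with_seed(seed, {
    counts <- matrix(0L, nrow = nrow(library), ncol = rounds)
    counts[, 1] <- rmultinom(1, bottleneck, freq0)[, 1]
    for (r in 2:rounds) {
      w <- counts[, r - 1] * library$survival
      if (sum(w) == 0) abort(sprintf("library extinct at round %d.", r))
      counts[, r] <- rmultinom(1, bottleneck, w)[, 1]
    }
    long <- tibble(
      variant = rep(library$variant, times = rounds),
      round = rep(seq_len(rounds), each = nrow(library)),
      count = as.integer(counts)
    ) %>% arrange(.data$variant, .data$round)
    list(
      counts = structure(long, class = c("round_count_table", class(long))),
      truth = mutate(library, freq0 = freq0)
    )
  })
}
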