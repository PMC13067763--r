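#' Default BEPI evaluation grid levels
#'
#' Seven C-to-T conversion levels spanning 2.5-100% and eight indel
#' frequency levels spanning 0-10%, the 7 x 8 = 56 scenario grid used to
#' compare candidate formulations. Counts and endpoints are fixed by the
#' evaluation design; interior points are configurable in [bepi_grid()].
#'
#' @name bepi_grid_levels
#' @return Numeric vector of levels in percent.
#' @export
bepi_c_levels <- function() c(2.5, 5, 10, 25, 50, 75, 100)

#' @rdname bepi_grid_levels
#' @export
bepi_indel_levels <- function() c(0, 0.5, 1, 2.5, 5, 7.5, 9, 10)

check_levels <- function(x, n, lo, hi, arg) {
  if (length(x) != n) {
    abort(sprintf("`%s` must have exactly %d levels (got %d).", arg, n, length(x)))
  }
  if (any(diff(x) <= 0)) abort(sprintf("`%s` must be strictly increasing.", arg))
  if (x[1] != lo || x[length(x)] != hi) {
    abort(sprintf("`%s` must span %s to %s percent.", arg, lo, hi))
  }
  as.numeric(x)
}

#' Evaluate a BEPI formula over the scenario grid
#'
#' Applies a formula to every combination of seven C-to-T conversion levels
#' (2.5-100%) and eight indel frequency levels (0-10%), the 56-point
#' scenario matrix used to screen the fifteen candidate formulations.
#'
#' @param formula Formula id, function, or `bepi_formula` (see
#'   [bepi_formula()]); default Formula 14.
#' @param c_levels Seven strictly increasing C-to-T percents from 2.5 to 100.
#' @param indel_levels Eight strictly increasing indel percents from 0 to 10.
#' @return A tibble of class `bepi_grid` with columns `c_to_t`, `indel`,
#'   `score` (56 rows).
#' @examples
#' g <- bepi_grid(14)
#' nrow(g) # 56
#' @export
bepi_grid <- function(formula = 14,
                      c_levels = bepi_c_levels(),
                      indel_levels = bepi_indel_levels()) {
  f <- bepi_formula(formula)
  c_levels <- check_levels(c_levels, 7L, 2.5, 100, "c_levels")
  indel_levels <- check_levels(indel_levels, 8L, 0, 10, "indel_levels")
  out <- tidyr::expand_grid(c_to_t = c_levels, indel = indel_levels)
  out$score <- f$fun(out$c_to_t, out$indel)
  if (any(!is.finite(out$score))) {
    abort("formula produced non-finite scores on the grid.")
  }
  structure(out, class = c("bepi_grid", class(out)), formula = f)
}

#' Sensitivity of a BEPI formula to indel frequency
#'
#' Profiles score versus indel frequency at fixed C-to-T conversion levels
#' (default 10/25/50/75%), the view used to judge whether a formulation has
#' balanced sensitivity across low and high indel regimes.
#'
#' @inheritParams bepi_grid
#' @param c_fixed Non-empty vector of fixed C-to-T percents.
#' @param indel_range Indel percents between 0 and 10 to sweep.
#' @return A tibble of class `bepi_sensitivity` with columns `c_to_t`,
#'   `indel`, `score`; one curve per fixed C-to-T level.
#' @export
bepi_sensitivity <- function(formula = 14,
                             c_fixed = c(10, 25, 50, 75),
                             indel_range = seq(0, 10, by = 0.5)) {
  f <- bepi_formula(formula)
  if (length(c_fixed) == 0L) abort("`c_fixed` must be non-empty.")
  if (length(indel_range) == 0L) abort("`indel_range` must be non-empty.")
  c_fixed <- assert_percent(c_fixed)
  if (any(indel_range < 0 | indel_range > 10)) {
    abort("`indel_range` must lie within [0, 10] percent.")
  }
  out <- tidyr::expand_grid(c_to_t = c_fixed, indel = as.numeric(indel_range))
  out$score <- f$fun(out$c_to_t, out$indel)
  structure(out, class = c("bepi_sensitivity", class(out)), formula = f)
}

#' Formula-selection criteria report
#'
#' Checks a BEPI formulation against the three selection criteria used to
#' pick the final formula: monotonicity in activity (score strictly
#' increasing in C-to-T at every fixed indel level of the grid),
#' monotonicity in indels (score strictly decreasing in indel frequency at
#' every fixed C-to-T level), and the high-efficiency ordering that a
#' 75%-conversion / 7.5%-indel editor must outscore a 50% / 5% one. Also
#' reports the low-indel discrimination `score(c, 0) - score(c, 1)` at a
#' reference conversion level, the margin separating indel-free from
#' low-indel conditions.
#'
#' @inheritParams bepi_grid
#' @param reference_c Reference C-to-T percent for the discrimination margin.
#' @return A one-row tibble of class `bepi_criteria`: `monotone_in_activity`,
#'   `monotone_in_indel`, `high_efficiency_ordering`,
#'   `low_indel_discrimination`, `notes`.
#' @examples
#' bepi_criteria(14)
#' @export
bepi_criteria <- function(formula = 14,
                          c_levels = bepi_c_levels(),
                          indel_levels = bepi_indel_levels(),
                          reference_c = 50) {
  f <- bepi_formula(formula)
  grid <- bepi_grid(f, c_levels, indel_levels)
  by_indel <- grid %>%
    group_by(.data$indel) %>%
    summarise(mono = all(diff(.data$score[order(.data$c_to_t)]) > 0))
  by_c <- grid %>%
    group_by(.data$c_to_t) %>%
    summarise(mono = all(diff(.data$score[order(.data$indel)]) < 0))
  ordering <- f$fun(75, 7.5) > f$fun(50, 5)
  discrim <- f$fun(reference_c, 0) - f$fun(reference_c, 1)
  notes <- character(0)
  if (!all(by_indel$mono)) notes <- c(notes, "not increasing in C-to-T at some indel level")
  if (!all(by_c$mono)) notes <- c(notes, "not strictly decreasing in indel at some C-to-T level")
  if (!ordering) notes <- c(notes, "fails (75, 7.5) > (50, 5) ordering")
  out <- tibble(
    formula = f$label,
    monotone_in_activity = all(by_indel$mono),
    monotone_in_indel = all(by_c$mono),
    high_efficiency_ordering = ordering,
    low_indel_discrimination = discrim,
    notes = if (length(notes)) paste(notes, collapse = "; ") else "all criteria met"
  )
  structure(out, class = c("bepi_criteria", class(out)))
}

#' Score and rank variants by BEPI
#'
#' @param data A data frame with columns `name`, `c_to_t`, `indel`
#'   (percents). Names must be unique.
#' @inheritParams bepi_grid
#' @param digits Decimals for the display-rounded `score_2dp` column
#'   (internal `score` stays full precision).
#' @return A tibble sorted by descending score with ties broken
#'   lexicographically by name; columns `rank`, `name`, `c_to_t`, `indel`,
#'   `score`, `score_2dp`.
#' @examples
#' bepi_rank(tibble::tibble(name = c("A", "B"),
#'                          c_to_t = c(50, 75), indel = c(5, 7.5)))
#' @export
bepi_rank <- function(data, formula = 14, digits = 2) {
  f <- bepi_formula(formula)
  data <- as_tibble(data)
  need <- c("name", "c_to_t", "indel")
  if (!all(need %in% names(data))) {
    abort("`data` needs columns name, c_to_t, indel.")
  }
  if (anyDuplicated(data$name)) abort("variant names must be unique.")
  out <- data %>%
    mutate(score = f$fun(assert_percent(.data$c_to_t),
                         assert_percent(.data$indel))) %>%
    arrange(desc(.data$score), .data$name) %>%
    mutate(rank = dplyr::row_number(),
           score_2dp = round(.data$score, digits)) %>%
    select("rank", "name", "c_to_t", "indel", "score", "score_2dp")
  out
}
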