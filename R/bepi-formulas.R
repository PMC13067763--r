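#' Base Editor Performance Index, Formula 14
#'
#' The selected BEPI formulation: `(c_to_t - indel) / exp(indel / 10)`.
#' The numerator penalizes indels linearly, which separates 0% from low
#' indel frequencies; the exponential denominator scales the penalty up
#' at high indel burden. Scores can be negative when the indel rate
#' exceeds the C-to-T conversion rate; negative values are returned
#' as-is rather than clamped, so pathological trade-offs stay visible.
#'
#' @param c_to_t C-to-T conversion in percent, within \[0, 100\].
#' @param indel Indel frequency in percent, within \[0, 100\].
#' @return Numeric score(s), full precision (round for display).
#' @examples
#' bepi_formula14(14.23, 1.82) # 10.34 at 2 decimals
#' bepi_formula14(50, 0)       # 50: zero penalty at zero indels
#' @seealso [bepi_formula11()], [bepi_grid()], [bepi_criteria()]
#' @export
bepi_formula14 <- function(c_to_t, indel) {
  c_to_t <- assert_percent(c_to_t)
  indel <- assert_percent(indel)
  (c_to_t - indel) / exp(indel / 10)
}

#' Base Editor Performance Index, Formula 11
#'
#' The runner-up BEPI formulation `c_to_t / exp(indel / 10)`: same
#' exponential indel penalty as Formula 14 but no linear term, so its
#' discrimination between 0% and low indel levels is weaker. Always
#' non-negative and never below Formula 14 at equal inputs.
#'
#' @inheritParams bepi_formula14
#' @return Numeric score(s).
#' @examples
#' bepi_formula11(50, 0)
#' bepi_formula11(29.64, 2.94)
#' @export
bepi_formula11 <- function(c_to_t, indel) {
  c_to_t <- assert_percent(c_to_t)
  indel <- assert_percent(indel)
  c_to_t / exp(indel / 10)
}

# registry of the fifteen formulations; only 11 and 14 are printed in full
# in the source study, so the other thirteen are placeholders users can fill
.bepi_registry <- new.env(parent = emptyenv())

bepi_registry_init <- function() {
  if (length(ls(.bepi_registry)) > 0L) return(invisible())
  families <- c(
    "arithmetic", "rational", "logarithmic", "exponential-decay"
  )
  for (id in 1:15) {
    assign(as.character(id), list(
      id = id, family = NA_character_, label = sprintf("Formula %d", id),
      fun = NULL
    ), envir = .bepi_registry)
  }
  assign("11", list(
    id = 11L, family = "exponential-decay",
    label = "Formula 11: c_to_t / exp(indel/10)",
    fun = bepi_formula11
  ), envir = .bepi_registry)
  assign("14", list(
    id = 14L, family = "exponential-decay",
    label = "Formula 14: (c_to_t - indel) / exp(indel/10)",
    fun = bepi_formula14
  ), envir = .bepi_registry)
  invisible(families)
}

#' Register a BEPI formula evaluator
#'
#' The package ships evaluators for Formulas 11 and 14, the two printed in
#' full; the remaining slots of the fifteen-formula family are placeholders.
#' Use this to plug in your own evaluator (a function of `c_to_t`, `indel`,
#' both in percent).
#'
#' @param id Integer 1-15.
#' @param fun Function `(c_to_t, indel) -> score`, vectorized.
#' @param family One of `"arithmetic"`, `"rational"`, `"logarithmic"`,
#'   `"exponential-decay"`.
#' @param label Display label.
#' @return The registered entry, invisibly.
#' @export
register_bepi_formula <- function(id, fun, family = NA_character_,
                                  label = sprintf("Formula %d", id)) {
  bepi_registry_init()
  if (!is.numeric(id) || length(id) != 1L || !(id %in% 1:15)) {
    abort("`id` must be a single integer in 1..15.")
  }
  if (!is.function(fun)) abort("`fun` must be a function(c_to_t, indel).")
  entry <- list(id = as.integer(id), family = family, label = label, fun = fun)
  assign(as.character(as.integer(id)), entry, envir = .bepi_registry)
  invisible(entry)
}

#' Look up a BEPI formula
#'
#' @param formula An integer id (1-15), a function `(c_to_t, indel)`, or a
#'   `bepi_formula` object.
#' @return A `bepi_formula` object (list with `id`, `family`, `label`, `fun`).
#' @export
bepi_formula <- function(formula = 14) {
  bepi_registry_init()
  if (inherits(formula, "bepi_formula")) return(formula)
  if (is.function(formula)) {
    out <- list(id = NA_integer_, family = NA_character_,
                label = "custom", fun = formula)
    class(out) <- "bepi_formula"
    return(out)
  }
  if (is.numeric(formula) && length(formula) == 1L && formula %in% 1:15) {
    entry <- get(as.character(as.integer(formula)), envir = .bepi_registry)
    if (is.null(entry$fun)) {
      abort(sprintf(
        "Formula %d has no registered evaluator (only 11 and 14 ship with the package); see ?register_bepi_formula.",
        as.integer(formula)))
    }
    class(entry) <- "bepi_formula"
    return(entry)
  }
  abort("`formula` must be an id in 1..15, a function, or a bepi_formula.")
}

#' List the BEPI formula registry
#'
#' @return A tibble with one row per formula slot: `id`, `family`, `label`,
#'   and whether an evaluator is available.
#' @export
bepi_formulas <- function() {
  bepi_registry_init()
  entries <- map(as.character(1:15), ~ get(.x, envir = .bepi_registry))
  tibble(
    id = map_int(entries, "id"),
    family = map_chr(entries, "family"),
    label = map_chr(entries, "label"),
    has_evaluator = map_lgl(entries, ~ !is.null(.x$fun))
  )
}

#' @export
print.bepi_formula <- function(x, ...) {
  cat("<bepi_formula> ", x$label, "\n", sep = "")
  invisible(x)
}
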