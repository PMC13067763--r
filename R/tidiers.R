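#' Tidiers and summaries for result objects
#'
#' broom-style accessors: `tidy()` returns the per-unit table of a result
#' (grid cells, positions, panel pairs, scan rows), `glance()` a one-row
#' summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name bepitools-tidiers
NULL

#' @rdname bepitools-tidiers
#' @export
tidy.bepi_grid <- function(x, ...) as_tibble(unclass_result(x))

#' @rdname bepitools-tidiers
#' @export
glance.bepi_grid <- function(x, ...) {
  tibble(formula = attr(x, "formula")$label,
         n_cells = nrow(x),
         min_score = min(x$score), max_score = max(x$score))
}

#' @rdname bepitools-tidiers
#' @export
tidy.bepi_criteria <- function(x, ...) as_tibble(unclass_result(x))

#' @rdname bepitools-tidiers
#' @export
tidy.quant_result <- function(x, ...) x$positions

#' @rdname bepitools-tidiers
#' @export
glance.quant_result <- function(x, ...) x$summary

#' @rdname bepitools-tidiers
#' @export
tidy.pocket_scan <- function(x, ...) as_tibble(unclass_result(x))

#' @rdname bepitools-tidiers
#' @export
glance.pocket_scan <- function(x, ...) {
  tibble(n_positions = nrow(x), key_site = attr(x, "key_site"),
         top_mean_area = x$mean_area[1])
}

#' @rdname bepitools-tidiers
#' @export
tidy.scheme_report <- function(x, ...) x$multiplicities

#' @rdname bepitools-tidiers
#' @export
glance.scheme_report <- function(x, ...) {
  tibble(n_amino_acids = nrow(x$multiplicities),
         n_codons = x$n_codons,
         n_stops = length(x$stops),
         balanced = x$balanced)
}

#' @rdname bepitools-tidiers
#' @export
tidy.enrichment_records <- function(x, ...) as_tibble(unclass_result(x))

#' @rdname bepitools-tidiers
#' @export
glance.enrichment_records <- function(x, ...) {
  tibble(n_variants = nrow(x),
         from = attr(x, "from"), to = attr(x, "to"),
         max_fold = if (nrow(x)) max(x$fold) else NA_real_)
}

# strip the result class so as_tibble gives a plain tibble
unclass_result <- function(x) {
  cls <- class(x)
  class(x) <- setdiff(cls, cls[1])
  x
}
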