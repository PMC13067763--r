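#' Plot methods
#'
#' `autoplot()` methods for the main result types: the BEPI scenario grid as
#' a heatmap, sensitivity profiles as one curve per fixed C-to-T level, the
#' per-position editing profile of a quantification, and the ranked pocket
#' scan.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name bepitools-plots
NULL

#' @rdname bepitools-plots
#' @export
autoplot.bepi_grid <- function(object, ...) {
  ggplot2::ggplot(as_tibble(unclass_result(object)),
                  ggplot2::aes(x = factor(.data$indel),
                               y = factor(.data$c_to_t),
                               fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(option = "viridis") +
    ggplot2::labs(x = "indel frequency (%)", y = "C-to-T conversion (%)",
                  fill = "BEPI",
                  title = attr(object, "formula")$label) +
    ggplot2::theme_minimal()
}

#' @rdname bepitools-plots
#' @export
autoplot.bepi_sensitivity <- function(object, ...) {
  ggplot2::ggplot(as_tibble(unclass_result(object)),
                  ggplot2::aes(x = .data$indel, y = .data$score,
                               colour = factor(.data$c_to_t))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "indel frequency (%)", y = "BEPI score",
                  colour = "C-to-T (%)",
                  title = attr(object, "formula")$label) +
    ggplot2::theme_minimal()
}

#' @rdname bepitools-plots
#' @export
autoplot.quant_result <- function(object, ...) {
  pos <- object$positions %>%
    tidyr::pivot_longer(cols = c("rate_c_to_t", "rate_c_to_a", "rate_c_to_g"),
                        names_to = "outcome", values_to = "rate") %>%
    mutate(outcome = sub("rate_c_to_", "C-to-", .data$outcome))
  ggplot2::ggplot(pos, ggplot2::aes(x = .data$position, y = 100 * .data$rate,
                                    fill = toupper(.data$outcome))) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::annotate("rect",
                      xmin = object$window[1] - 0.5,
                      xmax = object$window[2] + 0.5,
                      ymin = -Inf, ymax = Inf, alpha = 0.08) +
    ggplot2::labs(x = "PAM-relative protospacer position",
                  y = "conversion rate (%)", fill = "outcome") +
    ggplot2::theme_minimal()
}

#' @rdname bepitools-plots
#' @export
autoplot.pocket_scan <- function(object, ...) {
  df <- as_tibble(unclass_result(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$mean_area)) +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = df[df$rank == 1L, , drop = FALSE],
                        colour = "red", size = 3) +
    ggplot2::labs(x = "scanned position", y = "mean pocket area (Å²)") +
    ggplot2::theme_minimal()
}
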