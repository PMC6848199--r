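#' Plot cumulative origination curves
#'
#' Age runs right to left (old to young), so curves rise from the root
#' toward the present; younger classes sit lower and to the right.
#'
#' @param dist An `age_distribution` tibble.
#' @param tl The [timeline()] (supplies the left anchor at `root_age`).
#' @return A ggplot object.
#' @export
plot_age_curves <- function(dist, tl) {
  anchor <- dist |>
    dplyr::distinct(.data$class) |>
    dplyr::mutate(age_ma = root_age(tl), cum = 0)
  df <- dplyr::bind_rows(anchor, dist[, c("class", "age_ma", "cum")])
  ggplot2::ggplot(df, ggplot2::aes(.data$age_ma, .data$cum, colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = dist) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Divergence time (Ma)", y = "Cumulative share of genes",
                  colour = "Gene class") +
    ggplot2::theme_minimal()
}

#' @rdname plot_age_curves
#' @param object An `age_distribution` tibble.
#' @param ... Must include `tl`, the timeline.
#' @export
autoplot.age_distribution <- function(object, ...) {
  args <- list(...)
  tl <- args$tl
  if (is.null(tl)) abort("pass the timeline: autoplot(dist, tl = tl)")
  plot_age_curves(object, tl)
}

#' Plot a simultaneous confidence band for a curve difference
#'
#' @param x A `stoch_order_test` object.
#' @param tl Optional [timeline()] to place breakpoints on the Ma axis;
#'   defaults to plotting against taxon index.
#' @return A ggplot object.
#' @export
plot_order_band <- function(x, tl = NULL) {
  stopifnot(inherits(x, "stoch_order_test"))
  band <- x$band
  if (!is.null(tl)) {
    band$at <- tl$age_ma[band$taxon_index]
    xl <- "Divergence time (Ma)"
  } else {
    band$at <- band$taxon_index
    xl <- "Taxon breakpoint"
  }
  gg <- ggplot2::ggplot(band, ggplot2::aes(.data$at, .data$D)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$band_low,
                                      ymax = .data$band_high), alpha = 0.25) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = xl, y = sprintf("C[%s] - C[%s]", x$pair[1], x$pair[2]),
      title = sprintf("Simultaneous %d%% band; verdict: %s",
                      round(100 * (1 - x$alpha)), x$verdict)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(tl)) gg <- gg + ggplot2::scale_x_reverse()
  gg
}

#' @rdname plot_order_band
#' @param object A `stoch_order_test` object.
#' @param ... Passed options (`tl`).
#' @export
autoplot.stoch_order_test <- function(object, ...) {
  plot_order_band(object, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
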