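#' Plot a mismatch fit (observed bars, expected curve)
#' @param object A `mismatch_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mismatch_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$differences)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed), fill = "grey70",
                      colour = "grey30", width = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected), colour = "black",
                       linewidth = 0.8) +
    ggplot2::labs(x = "Pairwise differences", y = "Frequency",
                  title = sprintf("Mismatch distribution (tau = %.2f, SSD = %.4f)",
                                  object$tau, object$SSD)) +
    ggplot2::theme_minimal()
}

#' Plot a haplotype network
#'
#' Fruchterman–Reingold layout; observed haplotypes are drawn with area
#' proportional to frequency, median vectors as small open points.
#'
#' @param object A `haplo_network`.
#' @param seed Layout seed (default 1).
#' @param label Label observed nodes with their names (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.haplo_network <- function(object, seed = 1, label = TRUE, ...) {
  g <- igraph::graph_from_data_frame(object$edges, directed = FALSE,
                                     vertices = object$nodes$name)
  xy <- with_seed(seed, igraph::layout_with_fr(g,
    weights = 1 / pmax(igraph::E(g)$steps, 0.5)))
  nd <- object$nodes
  nd$x <- xy[, 1]; nd$y <- xy[, 2]
  ed <- object$edges
  ed$x <- nd$x[match(ed$from, nd$name)]
  ed$y <- nd$y[match(ed$from, nd$name)]
  ed$xend <- nd$x[match(ed$to, nd$name)]
  ed$yend <- nd$y[match(ed$to, nd$name)]
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey50") +
    ggplot2::geom_point(data = nd[!nd$is_median, ],
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$frequency),
      shape = 21, fill = "steelblue", colour = "grey20") +
    ggplot2::geom_point(data = nd[nd$is_median, ],
      ggplot2::aes(x = .data$x, y = .data$y),
      shape = 21, size = 1.5, fill = "white", colour = "grey20") +
    ggplot2::scale_size_area(max_size = 10) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "Frequency")
  if (label) {
    p <- p + ggplot2::geom_text(data = nd[!nd$is_median, ],
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
      size = 2.5, vjust = -1.2)
  }
  p
}

#' Bar chart of per-population diversity
#' @param div Result of [summarize_diversity()].
#' @param statistic `"h"` (default) or `"pi"`.
#' @return A ggplot.
#' @export
plot_diversity <- function(div, statistic = c("h", "pi")) {
  statistic <- match.arg(statistic)
  df <- div[div$population != "mean", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$population,
                                   y = .data[[statistic]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Population",
                  y = if (statistic == "h") "Haplotype diversity (h)"
                      else expression(pi)) +
    ggplot2::theme_minimal()
}
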