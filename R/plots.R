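#' @method autoplot glyc_entropy_curve
#' @export
autoplot.glyc_entropy_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$T, y = .data$entropy_bits)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::geom_point(color = "#2c7fb8") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "residence time T (log scale)",
                  y = "output entropy (bits)",
                  title = "Glycan variability vs compartment residence time") +
    ggplot2::theme_minimal()
}

#' @method autoplot glyc_distribution
#' @export
autoplot.glyc_distribution <- function(object, top = 15L, ...) {
  df <- utils::head(as.data.frame(object), top)
  df$oligomer <- factor(df$oligomer, levels = rev(df$oligomer))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$probability, y = .data$oligomer)) +
    ggplot2::geom_col(fill = "#41ab5d") +
    ggplot2::labs(x = "probability", y = NULL,
                  title = "Output oligomer distribution") +
    ggplot2::theme_minimal()
}

#' Plot a linkage network
#'
#' Draws monomer types on a circle with one arrow per enzyme from acceptor
#' type to donor type; trigger-disabled edges are dashed. Self-loops are
#' drawn as small loops above the node.
#'
#' @param lnet A [build_linkage_network()] result.
#' @return A ggplot object.
#' @export
plot_linkage_network <- function(lnet) {
  types <- sort(unique(c(lnet$from, lnet$to)))
  k <- length(types)
  ang <- seq(0, 2 * pi, length.out = k + 1L)[seq_len(k)]
  pos <- data.frame(type = types, x = cos(ang), y = sin(ang))
  ed <- as.data.frame(lnet)
  ed <- merge(ed, stats::setNames(pos, c("from", "x0", "y0")), by = "from")
  ed <- merge(ed, stats::setNames(pos, c("to", "x1", "y1")), by = "to")
  loops <- ed[ed$from == ed$to, , drop = FALSE]
  arcs <- ed[ed$from != ed$to, , drop = FALSE]
  p <- ggplot2::ggplot() +
    ggplot2::geom_point(data = pos, ggplot2::aes(.data$x, .data$y), size = 14,
                        shape = 21, fill = "grey92") +
    ggplot2::geom_text(data = pos, ggplot2::aes(.data$x, .data$y,
                                                label = .data$type), size = 3)
  if (nrow(arcs) > 0L) {
    p <- p + ggplot2::geom_curve(
      data = arcs,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, linetype = !.data$active),
      curvature = 0.2, arrow = ggplot2::arrow(length = ggplot2::unit(8, "pt")),
      color = "#e34a33"
    )
  }
  if (nrow(loops) > 0L) {
    p <- p + ggplot2::geom_point(
      data = loops,
      ggplot2::aes(x = .data$x0 * 1.25, y = .data$y0 * 1.25,
                   shape = !.data$active),
      size = 6, color = "#e34a33"
    ) +
      ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 13),
                                  guide = "none")
  }
  p + ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid",
                                                `TRUE` = "dashed"),
                                     guide = "none") +
    ggplot2::coord_equal(xlim = c(-1.6, 1.6), ylim = c(-1.6, 1.6)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Linkage network (circled loops mark runaway edges)")
}
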