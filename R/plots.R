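#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_ribbon
#'   geom_point geom_segment geom_raster geom_contour scale_fill_gradient2
#'   scale_colour_manual coord_polar coord_equal labs theme_minimal theme
#'   element_text scale_linewidth scale_size_area
NULL

#' @export
ggplot2::autoplot

#' Heatmap of signed gene-set scores
#'
#' Tissues by gene sets, colour fixed to the `[-1, +1]` scale so full
#' saturation means a p value at the permutation floor. Rows and columns
#' are ordered by Euclidean hierarchical clustering of the score matrix.
#'
#' @param object A `chap_gsa` tibble from [run_gsa()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot chap_gsa
#' @export
autoplot.chap_gsa <- function(object, ...) {
  wide <- tidyr::pivot_wider(object[, c("tissue", "set", "delta_gsa")],
                             names_from = "set", values_from = "delta_gsa")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$tissue
  row_ord <- hierarchical_order(m)$order
  col_ord <- if (ncol(m) > 1) hierarchical_order(t(m))$order else 1L
  df <- object
  df$tissue <- factor(df$tissue, levels = rownames(m)[row_ord])
  df$set <- factor(df$set, levels = colnames(m)[col_ord])
  ggplot(df, aes(x = .data$set, y = .data$tissue, fill = .data$delta_gsa)) +
    geom_tile() +
    scale_fill_gradient2(limits = c(-1, 1), low = "#2166AC", mid = "white",
                         high = "#B2182B", name = "ΔGSA") +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Polar plot of per-family M-score summaries
#'
#' Radial axes are the functional families; the blue (normal) and red
#' (tumor) lines are arm means and the translucent halos span the 5-95%
#' quantile range.
#'
#' @param object A `chap_polar` tibble from [polar_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot chap_polar
#' @export
autoplot.chap_polar <- function(object, ...) {
  df <- object
  df$family <- factor(df$family, levels = sort(unique(df$family)))
  ggplot(df, aes(x = .data$family, y = .data$mean,
                 group = .data$condition, colour = .data$condition,
                 fill = .data$condition)) +
    geom_ribbon(aes(ymin = .data$q05, ymax = .data$q95), alpha = 0.2,
                colour = NA) +
    geom_line() +
    geom_point(size = 1) +
    scale_colour_manual(values = c(normal = "#2166AC", tumor = "#B2182B"),
                        aesthetics = c("colour", "fill")) +
    coord_polar() +
    labs(x = NULL, y = "M-score") +
    theme_minimal()
}

#' Meta-network plot
#'
#' Meta-nodes sized by family member count and coloured by their value
#' (M-score or signed set score) on a symmetric scale; meta-edge width is
#' the number of bundled inter-family interactions.
#'
#' @param object A laid-out `family_meta_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot family_meta_network
#' @export
autoplot.family_meta_network <- function(object, ...) {
  if (!"x" %in% names(object$nodes)) object <- layout_meta(object)
  nodes <- object$nodes
  edges <- object$edges
  seg <- dplyr::mutate(
    edges,
    x = nodes$x[match(.data$from, nodes$family)],
    y = nodes$y[match(.data$from, nodes$family)],
    xend = nodes$x[match(.data$to, nodes$family)],
    yend = nodes$y[match(.data$to, nodes$family)])
  lim <- max(abs(nodes$value), 1e-9, na.rm = TRUE)
  ggplot() +
    geom_segment(data = seg,
                 aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend, linewidth = .data$weight),
                 colour = "grey70") +
    geom_point(data = nodes,
               aes(x = .data$x, y = .data$y, size = .data$size,
                   colour = .data$value)) +
    ggplot2::geom_text(data = nodes,
                       aes(x = .data$x, y = .data$y, label = .data$family),
                       vjust = -1.2, size = 3) +
    ggplot2::scale_colour_gradient2(limits = c(-lim, lim), low = "#2166AC",
                                    mid = "grey90", high = "#B2182B") +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    scale_size_area(max_size = 12) +
    coord_equal() +
    theme_minimal() +
    labs(x = NULL, y = NULL)
}

#' Topographic surface plot
#'
#' Raster + contour rendering of the interactome-guided landscape; colour
#' symmetric about zero so up- and downregulated families compare visually.
#'
#' @param object A `chap_surface` tibble from [topographic_surface()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot chap_surface
#' @export
autoplot.chap_surface <- function(object, ...) {
  lim <- max(abs(object$z), 1e-9)
  nodes <- attr(object, "nodes")
  p <- ggplot(object, aes(x = .data$x, y = .data$y)) +
    geom_raster(aes(fill = .data$z)) +
    geom_contour(aes(z = .data$z), colour = "grey40", linewidth = 0.2) +
    scale_fill_gradient2(limits = c(-lim, lim), low = "#2166AC",
                         mid = "white", high = "#B2182B", name = "z") +
    coord_equal() +
    theme_minimal() +
    labs(x = NULL, y = NULL)
  if (!is.null(nodes)) {
    p <- p + ggplot2::geom_text(
      data = nodes, aes(x = .data$x, y = .data$y, label = .data$family),
      size = 3)
  }
  p
}
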