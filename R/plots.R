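#' Plot a planar network
#'
#' Draws the links of the graph as segments with line width proportional to
#' weight -- the usual rendering of a digitized venation network.
#'
#' @param object A [planar_graph()].
#' @param max_linewidth Line width given to the heaviest link.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot planar_graph
#' @export
autoplot.planar_graph <- function(object, max_linewidth = 1.5, ...) {
  li <- object$links
  nd <- object$nodes
  df <- tibble::tibble(
    x = nd$x[match(li$from, nd$id)], y = nd$y[match(li$from, nd$id)],
    xend = nd$x[match(li$to, nd$id)], yend = nd$y[match(li$to, nd$id)],
    weight = li$weight
  )
  df <- df[is.finite(df$weight), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, xend = .data$xend,
                                   yend = .data$yend)) +
    ggplot2::geom_segment(ggplot2::aes(linewidth = .data$weight),
                          lineend = "round") +
    ggplot2::scale_linewidth(range = c(0.1, max_linewidth), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Plot a nesting tree as a merge-height dendrogram
#'
#' Leaves are spread on the x axis; each merge is drawn at the strength `h`
#' of the removed edge, so the vertical axis reads as the decomposition's
#' thickness cutoff.
#'
#' @param object A [nesting_tree].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nesting_tree
#' @export
autoplot.nesting_tree <- function(object, ...) {
  nd <- object$nodes
  n <- nrow(nd)
  leaf <- is.na(nd$child1)
  xpos <- numeric(n)
  ypos <- numeric(n)
  ## leaves in subtree order for a planar drawing
  order_leaves <- function(i) {
    if (is.na(nd$child1[i])) return(i)
    c(order_leaves(nd$child1[i]), order_leaves(nd$child2[i]))
  }
  lv <- order_leaves(n)
  xpos[lv] <- seq_along(lv)
  h0 <- min(nd$h[!leaf], na.rm = TRUE)
  ypos[leaf] <- h0 * 0.9
  for (i in which(!leaf)) {
    xpos[i] <- (xpos[nd$child1[i]] + xpos[nd$child2[i]]) / 2
    ypos[i] <- nd$h[i]
  }
  seg <- purrr::map_dfr(which(!leaf), function(i) {
    c1 <- nd$child1[i]; c2 <- nd$child2[i]
    tibble::tibble(
      x = c(xpos[c1], xpos[c1], xpos[c2]),
      xend = c(xpos[c1], xpos[c2], xpos[c2]),
      y = c(ypos[c1], ypos[i], ypos[i]),
      yend = c(ypos[i], ypos[i], ypos[c2])
    )
  })
  ggplot2::ggplot(seg, ggplot2::aes(.data$x, .data$y, xend = .data$xend,
                                    yend = .data$yend)) +
    ggplot2::geom_segment(linewidth = 0.3) +
    ggplot2::labs(x = "terminal loops", y = "removed edge strength h") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot an averaged-asymmetry profile
#'
#' @param profile Output of [asymmetry_profile()] (the node scatter carried
#'   in its `"scatter"` attribute is underlaid when present).
#' @return A ggplot object.
#' @export
plot_asymmetry_profile <- function(profile) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(.data$log2_d, .data$lambda))
  sc <- attr(profile, "scatter")
  if (!is.null(sc)) {
    p <- p + ggplot2::geom_point(
      data = sc, ggplot2::aes(.data$log2_d, .data$asymmetry),
      alpha = 0.15, size = 0.5
    )
  }
  p + ggplot2::geom_line(colour = "red") +
    ggplot2::labs(x = expression(log[2] ~ d),
                  y = expression(Lambda(d))) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a cumulative size distribution
#'
#' @param series Output of [cumulative_size_distribution()] or
#'   [adjusted_csd()].
#' @param loglog Draw on log-log axes.
#' @return A ggplot object.
#' @export
plot_csd <- function(series, loglog = !("p" %in% names(series))) {
  ycol <- if ("p" %in% names(series)) "p" else "p_adj"
  p <- ggplot2::ggplot(series, ggplot2::aes(.data$a, .data[[ycol]])) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "a",
                  y = if (ycol == "p") "P(A > a)" else "a P(A > a)") +
    ggplot2::theme_minimal()
  if (loglog) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}

#' Overlay a segmentation on the source graph
#'
#' Colours each terminal face of the graph by its segment.
#'
#' @param g The decomposed [planar_graph()] (pruned, as used for the tree).
#' @param t The [nesting_tree] of `g`.
#' @param segmentation Output of [segment_tree()].
#' @return A ggplot object.
#' @export
plot_segmentation <- function(g, t, segmentation) {
  g2 <- prune_tree_components(g)
  fs <- face_structure(g2)
  nd <- t$nodes
  leafs <- nd[!is.na(nd$face) & !nd$exterior, ]
  polys <- purrr::map_dfr(seq_len(nrow(leafs)), function(i) {
    f <- leafs$face[i]
    vs <- fs$cycle[[f]]
    seg <- segmentation$segment[match(f, segmentation$face)]
    tibble::tibble(x = g2$nodes$x[vs], y = g2$nodes$y[vs],
                   face = f, segment = seg)
  })
  ggplot2::ggplot(polys, ggplot2::aes(.data$x, .data$y, group = .data$face,
                                      fill = factor(.data$segment))) +
    ggplot2::geom_polygon(colour = "grey30", linewidth = 0.1) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "segment") +
    ggplot2::theme_void()
}
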