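## ggplot2 views of the result objects. Layout for the tree plot: terminals
## are spaced evenly left-to-right, internal nodes sit above the midpoint of
## their children, depth runs downwards.

tree_layout <- function(tree) {
  nodes <- tidy(tree)
  x <- rep(NA_real_, nrow(nodes))
  leaf_ids <- terminal_ids(tree)
  ## in-order positions of terminals
  order_leaves <- function(id) {
    nd <- tree$nodes[[id + 1L]]
    if (is.null(nd$children)) return(id)
    c(order_leaves(nd$children[1L]), order_leaves(nd$children[2L]))
  }
  pos <- seq_along(leaf_ids)
  names(pos) <- as.character(order_leaves(0L))
  x[match(as.integer(names(pos)), nodes$node_id)] <- pos
  for (i in rev(seq_len(nrow(nodes)))) {
    nd <- tree$nodes[[i]]
    if (!is.null(nd$children)) {
      x[i] <- mean(x[match(nd$children, nodes$node_id)])
    }
  }
  nodes$x <- x
  nodes$y <- -nodes$depth
  nodes
}

#' Plot a regression tree
#'
#' Draws the tree with node boxes (id, size, mean of the dependent variable)
#' and split labels on the left edges.
#'
#' @param object An `rtree`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.rtree <- function(object, ...) {
  nodes <- tree_layout(object)
  edges <- nodes %>%
    filter(!.data$terminal) %>%
    tidyr::pivot_longer(c("child_left", "child_right"), values_to = "child") %>%
    left_join(nodes %>% select(child = "node_id", xend = "x", yend = "y"),
              by = "child")
  lab <- nodes %>%
    mutate(label = sprintf("%d\nn=%d\nmean=%.1f", .data$node_id, .data$n,
                           .data$mean))
  split_lab <- nodes %>%
    filter(!is.na(.data$split_predictor)) %>%
    mutate(label = ifelse(.data$split_kind == "numeric-threshold",
                          sprintf("%s <= %.3g", .data$split_predictor,
                                  .data$threshold),
                          sprintf("%s subset", .data$split_predictor)))
  ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(xend = .data$xend, yend = .data$yend),
                          colour = "grey50") +
    ggplot2::geom_label(data = lab, ggplot2::aes(label = .data$label),
                        size = 3) +
    ggplot2::geom_text(data = split_lab,
                       ggplot2::aes(label = .data$label, y = .data$y - 0.35),
                       size = 3, colour = "grey30") +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("%s ~ %s", object$dependent,
                                  paste(object$predictors, collapse = " + ")))
}

#' Bar chart of variable importance
#'
#' @param importance A table from [variable_importance()].
#' @return A ggplot object.
#' @export
plot_importance <- function(importance) {
  ggplot2::ggplot(importance,
                  ggplot2::aes(x = .data$scaled_importance,
                               y = stats::reorder(.data$predictor,
                                                  .data$scaled_importance))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "scaled importance (best = 100)", y = NULL)
}

#' Slope chart of importance ranks at two time points
#'
#' Visualises reprioritization: each predictor's rank at the two anchored
#' trees, with rank changes highlighted.
#'
#' @param report A table from [reprioritization_report()].
#' @return A ggplot object.
#' @export
plot_reprioritization <- function(report) {
  long <- report %>%
    tidyr::pivot_longer(c("rank_t1", "rank_t2"), names_to = "time",
                        values_to = "rank") %>%
    mutate(time = ifelse(.data$time == "rank_t1", "t1", "t2"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$rank,
                                     group = .data$predictor,
                                     colour = .data$predictor)) +
    ggplot2::geom_line(ggplot2::aes(linetype = !.data$flagged[
      match(.data$predictor, report$predictor)])) +
    ggplot2::geom_point() +
    ggplot2::scale_y_reverse(breaks = seq_len(max(long$rank))) +
    ggplot2::guides(linetype = "none") +
    ggplot2::labs(x = NULL, y = "importance rank (1 = most important)")
}
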