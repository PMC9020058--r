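#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a subgraph solution into a per-node tibble
#'
#' @param x A `deregnet_solution`.
#' @param ... Unused.
#' @return Tibble with columns `node`, `score`, `is_root`.
#' @export
tidy.deregnet_solution <- function(x, ...) {
  tibble::tibble(node = x$nodes, score = unname(x$score[x$nodes]),
                 is_root = x$nodes == x$root)
}

#' One-row summary of a subgraph solution
#'
#' @param x A `deregnet_solution`.
#' @param ... Unused.
#' @return One-row tibble with the objective (average score), total score,
#'   size, root, rank, convergence flag and iteration count.
#' @export
glance.deregnet_solution <- function(x, ...) {
  tibble::tibble(objective = x$objective, total_score = x$total_score,
                 n_nodes = length(x$nodes), root = x$root, rank = x$rank,
                 converged = x$converged, iterations = x$iterations,
                 sense = x$sense)
}

#' Plot a solution subgraph
#'
#' Draws the induced subgraph with nodes colored by score and the root
#' highlighted.
#'
#' @param object A `deregnet_solution`.
#' @param g The underlying igraph network.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deregnet_solution <- function(object, g, ...) {
  sub <- union_summary(list(object), g)
  set.seed(1L)
  lay <- igraph::layout_with_fr(sub)
  nodes <- tibble::tibble(name = igraph::V(sub)$name, x = lay[, 1L],
                          y = lay[, 2L],
                          score = igraph::V(sub)$score,
                          is_root = igraph::V(sub)$is_root)
  el <- igraph::as_edgelist(sub)
  edges <- tibble::tibble(
    x = nodes$x[match(el[, 1L], nodes$name)],
    y = nodes$y[match(el[, 1L], nodes$name)],
    xend = nodes$x[match(el[, 2L], nodes$name)],
    yend = nodes$y[match(el[, 2L], nodes$name)])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          color = "grey60",
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     color = .data$score,
                                     shape = .data$is_root), size = 4) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$name),
                       vjust = -1.2, size = 3) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17)) +
    ggplot2::theme_void() +
    ggplot2::labs(color = "score", shape = "root")
}
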