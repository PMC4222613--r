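#' Tidy a machine flux analysis
#'
#' @param x A `machine_flux` object from [machine_fluxes()].
#' @param ... Unused.
#' @return Tibble with one row per one-way flux (`flux`, `mfpt`, `value`).
#' @export
tidy.machine_flux <- function(x, ...) x$one_way

#' One-row summary of a machine flux analysis
#'
#' @inheritParams tidy.machine_flux
#' @return Tibble with `J1`, `J2`, `epsilon`, `eta`, `method`.
#' @export
glance.machine_flux <- function(x, ...) {
  tibble::tibble(J1 = x$J1, J2 = x$J2, epsilon = x$epsilon, eta = x$eta,
                 method = x$method)
}

#' Tidy a stochastic network into its edge table
#'
#' @param x A [stoch_net()].
#' @param ... Unused.
#' @return The edge tibble.
#' @export
tidy.stoch_net <- function(x, ...) x$edges

#' One-row summary of a stochastic network
#'
#' @inheritParams tidy.stoch_net
#' @return Tibble with node/edge/self-loop counts and the number of
#'   independent cycles of the undirected support.
#' @export
glance.stoch_net <- function(x, ...) {
  u <- undirected_support(x)
  g <- igraph::graph_from_data_frame(
    data.frame(from = u$a + 1L, to = u$b + 1L), directed = FALSE,
    vertices = data.frame(name = seq_len(x$n_nodes)))
  comp <- igraph::components(g)$no
  tibble::tibble(
    n_nodes = x$n_nodes,
    n_edges = nrow(x$edges),
    n_self_loops = sum(x$edges$from == x$edges$to),
    n_support_edges = nrow(u),
    n_components = comp,
    n_cycles = nrow(u) - x$n_nodes + comp)
}

#' Plot a stochastic network
#'
#' Force-directed layout of the undirected support with ggplot2; edge
#' width scales with transition probability, self-loops are shown as
#' haloed nodes.
#'
#' @param object A [stoch_net()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stoch_net <- function(object, ...) {
  u <- undirected_support(object)
  g <- igraph::graph_from_data_frame(
    data.frame(from = u$a + 1L, to = u$b + 1L), directed = FALSE,
    vertices = data.frame(name = seq_len(object$n_nodes)))
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(node = 0:(object$n_nodes - 1L),
                          x = xy[, 1], y = xy[, 2],
                          waiting = node %in% object$edges$from[object$edges$from == object$edges$to])
  ed <- object$edges[object$edges$from != object$edges$to, , drop = FALSE]
  seg <- tibble::tibble(
    x = nodes$x[ed$from + 1L], y = nodes$y[ed$from + 1L],
    xend = nodes$x[ed$to + 1L], yend = nodes$y[ed$to + 1L], p = ed$p)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linewidth = .data$p),
                          colour = "grey50", alpha = 0.7) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = .data$waiting), size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$node),
                       vjust = -1, size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 10),
                                guide = "none") +
    ggplot2::theme_void()
}

#' Plot the one-way fluxes of a machine analysis
#'
#' @param object A `machine_flux` object.
#' @param ... Unused.
#' @return A ggplot bar chart of the four one-way fluxes.
#' @export
autoplot.machine_flux <- function(object, ...) {
  d <- object$one_way
  ggplot2::ggplot(d, ggplot2::aes(x = .data$flux, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "one-way flux (1/step)",
                  subtitle = sprintf("degree of coupling = %.3f", object$epsilon)) +
    ggplot2::theme_minimal()
}
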