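#' Tidy an mfd result into its decomposition tibble
#'
#' @param x An `mfd_result` from [mfd()].
#' @param ... Unused.
#' @return A tibble with one row per decomposition element: `element`,
#'   `class`, `weight`, `length` (number of edges) and `nodes`
#'   (list-column). Zero rows when the problem was infeasible or timed
#'   out.
#' @export
tidy.mfd_result <- function(x, ...) {
  d <- x$decomposition
  if (is.null(d)) {
    return(tibble::tibble(element = integer(), class = character(),
                          weight = numeric(), length = integer(),
                          nodes = list()))
  }
  dplyr::mutate(d, length = lengths(.data$nodes) - 1L,
                .after = "weight")
}

#' One-row summary of an mfd result
#'
#' @param x An `mfd_result` from [mfd()].
#' @param ... Unused.
#' @return A one-row tibble: instance, variant, method, search strategy,
#'   status, minimum k, constraint-generation iterations, number of
#'   probes, and wall-clock seconds.
#' @export
glance.mfd_result <- function(x, ...) {
  tibble::tibble(
    instance = x$instance,
    variant = x$variant,
    method = x$method,
    search = x$search,
    status = x$status,
    k = x$k %||% NA_integer_,
    iterations = x$iterations %||% NA_integer_,
    probes = if (is.null(x$probes)) 0L else nrow(x$probes),
    wallclock = x$wallclock
  )
}

#' Plot a flow network
#'
#' Nodes are laid out with a deterministic Sugiyama-style layered layout
#' and edges are labelled with their flow values.
#'
#' @param object A [flow_network()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flow_network <- function(object, ...) {
  g <- igraph::graph_from_data_frame(object$edges[, c("from", "to")],
                                     vertices = object$nodes)
  xy <- igraph::layout_with_sugiyama(g)$layout
  pos <- tibble::tibble(node = object$nodes,
                        x = xy[, 2], y = xy[, 1])
  seg <- dplyr::left_join(object$edges, pos, by = c("from" = "node"))
  seg <- dplyr::left_join(seg, pos, by = c("to" = "node"),
                          suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend,
                   linewidth = .data$flow),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "in")),
      colour = "grey50", alpha = 0.7
    ) +
    ggplot2::geom_label(data = pos,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$node)) +
    ggplot2::scale_linewidth(range = c(0.3, 2), name = "flow") +
    ggplot2::theme_void() +
    ggplot2::labs(title = object$name)
}

#' Plot the per-edge composition of a decomposition
#'
#' Stacked per-edge bars showing how the weighted elements add up to each
#' edge's flow value.
#'
#' @param object An `mfd_result` with a decomposition.
#' @param net The [flow_network()] it decomposes.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mfd_result <- function(object, net, ...) {
  d <- object$decomposition
  if (is.null(d)) rlang::abort("result carries no decomposition")
  rows <- purrr::map_dfr(seq_len(nrow(d)), function(i) {
    usage <- walk_edge_usage(net, d$nodes[[i]])
    tibble::tibble(
      edge = paste0(net$edges$from, "→", net$edges$to),
      contribution = usage * d$weight[i],
      element = factor(paste0("element ", i, " (", d$class[i], ")"))
    )
  })
  rows <- dplyr::filter(rows, .data$contribution > 0)
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$edge, y = .data$contribution,
                                     fill = .data$element)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "weighted usage",
                  title = paste0(object$instance, ": ", object$variant,
                                 " decomposition, k = ", object$k)) +
    ggplot2::theme_minimal()
}
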