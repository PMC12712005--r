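#' Construct a flow network from an edge table
#'
#' A flow network is a weakly connected directed graph with a unique source
#' `s` (in-degree 0), a unique sink `t` (out-degree 0) and a positive integer
#' flow value on every edge, satisfying conservation of flow at every node
#' other than `s` and `t` (incoming flow equals outgoing flow). Source and
#' sink are inferred, never declared: a graph with several in-degree-0 or
#' out-degree-0 nodes is rejected rather than silently repaired.
#'
#' @param edges A data frame with columns `from`, `to` and `flow`
#'   (positive integers). Node identifiers are arbitrary whitespace-free
#'   character tokens; duplicate `(from, to)` pairs and self-loops are
#'   invalid.
#' @param name Optional instance label.
#' @param strict If `TRUE` (default), invalid input is an error. If
#'   `FALSE`, the (possibly invalid) object is returned with the validation
#'   report attached as attribute `"validation"`, for inspection tooling.
#' @return A `flow_network` object.
#' @examples
#' net <- flow_network(data.frame(
#'   from = c("s", "a", "b", "c", "a"),
#'   to   = c("a", "b", "c", "a", "t"),
#'   flow = c(1, 2, 2, 2, 1)
#' ))
#' net
#' @export
flow_network <- function(edges, name = "instance", strict = TRUE) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("from", "to", "flow") %in% names(edges)))
  edges <- dplyr::transmute(
    edges,
    from = as.character(.data$from),
    to = as.character(.data$to),
    flow = as.numeric(.data$flow)
  )
  nodes <- unique(c(rbind(edges$from, edges$to)))
  report <- validate_flow_network(edges)
  if (strict && !report$ok) {
    msg <- paste(report$violations$kind, report$violations$detail,
                 sep = ": ", collapse = "; ")
    rlang::abort(paste0("invalid flow network '", name, "': ", msg))
  }
  src <- setdiff(nodes, edges$to)
  snk <- setdiff(nodes, edges$from)
  net <- structure(
    list(
      name = name,
      nodes = nodes,
      edges = edges,
      source = if (length(src) == 1) src else NA_character_,
      sink = if (length(snk) == 1) snk else NA_character_,
      n = length(nodes),
      m = nrow(edges)
    ),
    class = "flow_network"
  )
  if (!strict) attr(net, "validation") <- report
  net
}

#' Validate a candidate flow network
#'
#' Checks every defining invariant of a flow network and reports all
#' violations (nothing is raised). Flagged kinds: `nonpositive_flow`,
#' `self_loop`, `duplicate_edge`, `multi_source`, `multi_sink`,
#' `conservation` (exactly the internal nodes where in-flow differs from
#' out-flow) and `disconnected`.
#'
#' @param x A `flow_network`, or a data frame of edges as accepted by
#'   [flow_network()].
#' @return A list with `ok` (logical) and `violations`, a tibble with
#'   columns `kind`, `where`, `detail`. `ok` is `TRUE` iff `violations` is
#'   empty.
#' @export
validate_flow_network <- function(x) {
  edges <- if (inherits(x, "flow_network")) x$edges else tibble::as_tibble(x)
  viol <- list()
  bad <- function(kind, where, detail) {
    viol[[length(viol) + 1L]] <<- tibble::tibble(
      kind = kind, where = where, detail = detail
    )
  }
  f <- edges$flow
  not_pos <- which(!is.finite(f) | f <= 0 | f != round(f))
  for (i in not_pos) {
    bad("nonpositive_flow", paste0(edges$from[i], "->", edges$to[i]),
        paste0("flow must be a positive integer, got ", f[i]))
  }
  loops <- which(edges$from == edges$to)
  for (i in loops) {
    bad("self_loop", edges$from[i], "self-loop edge")
  }
  key <- paste(edges$from, edges$to)
  dups <- unique(key[duplicated(key)])
  for (k in dups) {
    bad("duplicate_edge", k, "parallel edges are not supported")
  }
  nodes <- unique(c(rbind(edges$from, edges$to)))
  src <- setdiff(nodes, edges$to)
  snk <- setdiff(nodes, edges$from)
  if (length(src) != 1) {
    bad("multi_source", paste(src, collapse = ","),
        paste0(length(src), " nodes with in-degree 0 (need exactly 1)"))
  }
  if (length(snk) != 1) {
    bad("multi_sink", paste(snk, collapse = ","),
        paste0(length(snk), " nodes with out-degree 0 (need exactly 1)"))
  }
  if (length(src) == 1 && length(snk) == 1 && length(not_pos) == 0) {
    internal <- setdiff(nodes, c(src, snk))
    for (v in internal) {
      fin <- sum(f[edges$to == v])
      fout <- sum(f[edges$from == v])
      if (fin != fout) {
        bad("conservation", v, paste0("in-flow ", fin, " != out-flow ", fout))
      }
    }
  }
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                       vertices = nodes)
    if (igraph::components(g, mode = "weak")$no > 1) {
      bad("disconnected", "", "underlying undirected graph is not connected")
    }
  }
  violations <- if (length(viol)) dplyr::bind_rows(viol) else
    tibble::tibble(kind = character(), where = character(), detail = character())
  list(ok = nrow(violations) == 0L, violations = violations)
}

#' @export
print.flow_network <- function(x, ...) {
  cat("<flow_network> ", x$name, ": ", x$n, " nodes, ", x$m, " edges, ",
      x$source, " -> ", x$sink, "\n", sep = "")
  print(x$edges, n = 10)
  invisible(x)
}

#' @export
as_tibble.flow_network <- function(x, ...) x$edges

## ---- internal indexing helpers ----------------------------------------

## integer endpoints and per-node in/out edge index lists
net_index <- function(net) {
  ei_from <- match(net$edges$from, net$nodes)
  ei_to <- match(net$edges$to, net$nodes)
  out_e <- lapply(seq_len(net$n), function(v) which(ei_from == v))
  in_e <- lapply(seq_len(net$n), function(v) which(ei_to == v))
  list(ei_from = ei_from, ei_to = ei_to, out_e = out_e, in_e = in_e,
       s = match(net$source, net$nodes), t = match(net$sink, net$nodes))
}

## total flow out of the source (sum of element weights in any decomposition)
source_outflow <- function(net) {
  sum(net$edges$flow[net$edges$from == net$source])
}

## is the network acyclic?
net_is_dag <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     vertices = net$nodes)
  igraph::is_dag(g)
}
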