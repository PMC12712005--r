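#' Build a decomposition tibble from node sequences and weights
#'
#' A decomposition is a tibble with one row per element: `element` (index),
#' `class` (as reported by [classify_walk()]), `weight` (positive integer)
#' and `nodes` (list-column of node-identifier vectors).
#'
#' @param net The [flow_network()] the elements live on.
#' @param nodes A list of character vectors, each a node sequence.
#' @param weights Positive integer weights, one per element.
#' @return A decomposition tibble.
#' @export
decomposition <- function(net, nodes, weights) {
  stopifnot(length(nodes) == length(weights))
  tibble::tibble(
    element = seq_along(nodes),
    class = vapply(nodes, function(ns) classify_walk(net, ns), character(1)),
    weight = as.numeric(weights),
    nodes = nodes
  )
}

#' Classify a node sequence as path, cycle, trail, walk or invalid
#'
#' * `path`: an s-t sequence repeating no node;
#' * `cycle`: first node equals last node, no other repeats (a cycle never
#'   contains the source or the sink, which lack in- or out-edges);
#' * `trail`: an s-t sequence with a repeated node but no repeated edge;
#' * `walk`: an s-t sequence with at least one repeated edge;
#' * `invalid`: uses a non-edge of the network or has wrong endpoints.
#'
#' @param net A [flow_network()].
#' @param nodes Character vector of consecutive nodes.
#' @return One of `"path"`, `"cycle"`, `"trail"`, `"walk"`, `"invalid"`.
#' @export
classify_walk <- function(net, nodes) {
  if (length(nodes) < 2) return("invalid")
  key <- paste(net$edges$from, net$edges$to)
  steps <- paste(nodes[-length(nodes)], nodes[-1])
  if (!all(steps %in% key)) return("invalid")
  is_closed <- nodes[1] == nodes[length(nodes)]
  if (is_closed) {
    inner <- nodes[-length(nodes)]
    if (anyDuplicated(inner)) return("invalid")
    return("cycle")
  }
  if (nodes[1] != net$source || nodes[length(nodes)] != net$sink) {
    return("invalid")
  }
  if (anyDuplicated(steps)) return("walk")
  if (anyDuplicated(nodes)) return("trail")
  "path"
}

## per-edge usage counts W_i(u,v) of a node sequence (vector over edge index)
walk_edge_usage <- function(net, nodes) {
  usage <- numeric(net$m)
  if (length(nodes) < 2) return(usage)
  key <- paste(net$edges$from, net$edges$to)
  steps <- paste(nodes[-length(nodes)], nodes[-1])
  tab <- table(match(steps, key))
  usage[as.integer(names(tab))] <- as.numeric(tab)
  usage
}

## which element classes are admissible under each problem variant
admissible_classes <- function(variant) {
  switch(variant,
    fdpc = c("path", "cycle"),
    fdt = c("path", "trail"),
    fdw = c("path", "trail", "walk"),
    rlang::abort(paste0("unknown variant: ", variant))
  )
}

#' Check a decomposition against a flow network
#'
#' Recomputes, in exact integer arithmetic, the per-edge residual
#' `sum_i w_i W_i(u,v) - f_uv` and checks that every element's class is
#' admissible for the problem variant (`fdpc`: path or cycle; `fdt`: path
#' or trail; `fdw`: any valid s-t element or cycle-free superset thereof).
#'
#' @param net A [flow_network()].
#' @param dec A decomposition tibble (see [decomposition()]).
#' @param variant One of `"fdpc"`, `"fdt"`, `"fdw"`.
#' @return A list with `ok`, `residuals` (tibble `from`, `to`, `residual`)
#'   and `class_ok` per element. Nothing is raised.
#' @export
check_decomposition <- function(net, dec, variant = c("fdpc", "fdt", "fdw")) {
  variant <- match.arg(variant)
  usage <- vapply(dec$nodes, function(ns) walk_edge_usage(net, ns),
                  numeric(net$m))
  total <- if (nrow(dec) == 0) numeric(net$m) else
    as.numeric(matrix(usage, nrow = net$m) %*% dec$weight)
  residual <- total - net$edges$flow
  classes <- vapply(dec$nodes, function(ns) classify_walk(net, ns), character(1))
  class_ok <- classes %in% admissible_classes(variant)
  weight_ok <- all(dec$weight >= 1 & dec$weight == round(dec$weight))
  list(
    ok = all(residual == 0) && all(class_ok) && weight_ok,
    residuals = tibble::tibble(from = net$edges$from, to = net$edges$to,
                               residual = residual),
    class_ok = class_ok
  )
}

#' Can an edge set be ordered into a single s-t trail?
#'
#' Direct check of the two set-level conditions: (1) signed conservation
#' (net in-degree minus out-degree is +1 at the sink, -1 at the source,
#' 0 elsewhere) and (2) every strongly connected component of the induced
#' subgraph, other than the singleton sink, has a selected edge leaving its
#' edge set. Implemented independently of any ILP machinery so it can
#' cross-validate the solvers.
#'
#' @param net A [flow_network()].
#' @param edge_set Integer vector of edge indices (rows of `net$edges`).
#' @return `TRUE` or `FALSE`. The empty set is vacuously `TRUE` (an unused
#'   element).
#' @export
is_trail_set <- function(net, edge_set) {
  edge_set <- unique(as.integer(edge_set))
  if (length(edge_set) == 0) return(TRUE)
  usage <- numeric(net$m)
  usage[edge_set] <- 1
  if (!signed_conservation_ok(net, usage)) return(FALSE)
  sel <- net$edges[edge_set, ]
  vn <- unique(c(sel$from, sel$to))
  g <- igraph::graph_from_data_frame(sel[, c("from", "to")], vertices = vn)
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  for (ci in seq_len(comp$no)) {
    cn <- names(memb)[memb == ci]
    internal <- which(sel$from %in% cn & sel$to %in% cn)
    if (identical(cn, net$sink)) next
    ## outgoing selected edge leaving the component's edge set
    outgoing <- which(sel$from %in% cn)
    if (length(setdiff(outgoing, internal)) == 0) {
      ## a component with no escape: only acceptable if it is a single node
      ## with no internal edge and no selected out-edge at all would already
      ## break conservation; treat as violation when it has internal edges
      ## or any node other than the sink
      if (length(internal) > 0 || !identical(cn, net$sink)) return(FALSE)
    }
  }
  TRUE
}

#' Can an edge multiset be ordered into a single s-t walk?
#'
#' Checks (1) signed conservation of the multiplicities and (2) that every
#' node incident to a selected edge is reachable from the source using
#' selected edges.
#'
#' @param net A [flow_network()].
#' @param usage Numeric vector of per-edge multiplicities (length `m`).
#' @return `TRUE` or `FALSE`; the all-zero multiset is vacuously `TRUE`.
#' @export
is_walk_set <- function(net, usage) {
  stopifnot(length(usage) == net$m)
  if (all(usage == 0)) return(TRUE)
  if (!signed_conservation_ok(net, usage)) return(FALSE)
  sel <- net$edges[usage > 0, ]
  vn <- unique(c(sel$from, sel$to))
  if (!(net$source %in% vn)) return(FALSE)
  g <- igraph::graph_from_data_frame(sel[, c("from", "to")], vertices = vn)
  reach <- igraph::subcomponent(g, net$source, mode = "out")
  length(reach) == length(vn)
}

signed_conservation_ok <- function(net, usage) {
  for (v in net$nodes) {
    bal <- sum(usage[net$edges$to == v]) - sum(usage[net$edges$from == v])
    want <- if (v == net$sink) 1 else if (v == net$source) -1 else 0
    if (bal != want) return(FALSE)
  }
  TRUE
}

#' Exhaustive minimum-k oracle for tiny instances
#'
#' Finds the true minimum decomposition size by exhaustive backtracking over
#' admissible elements and integer weights, entirely independent of the ILP
#' solvers. Candidate elements are enumerated as edge-usage vectors through
#' a state-space search over (current node, usage-so-far) states, which
#' collapses the many orderings of one multiset into a single candidate.
#' At each recursion step the lexicographically first edge with positive
#' residual flow must be covered by the next chosen element (some element
#' of any remaining decomposition covers it, and element order is free, so
#' this prunes permutations without losing solutions). Failed
#' (residual, remaining-k) states are memoized.
#'
#' Guarded to tiny instances: `m <= 10` edges, all flows `<= 8`,
#' `k_cap <= 6`.
#'
#' @param net A [flow_network()].
#' @param variant One of `"fdpc"`, `"fdt"`, `"fdw"`.
#' @param k_cap Largest k to try.
#' @return The minimum k as an integer, or `Inf` if no decomposition of
#'   size `<= k_cap` exists.
#' @export
brute_force_min_k <- function(net, variant = c("fdpc", "fdt", "fdw"),
                              k_cap = 6L) {
  variant <- match.arg(variant)
  if (net$m > 10 || max(net$edges$flow) > 8 || k_cap > 6) {
    rlang::abort("oracle guard: needs m <= 10, max flow <= 8, k_cap <= 6")
  }
  idx <- net_index(net)
  f <- net$edges$flow
  failed <- new.env(parent = emptyenv())

  feasible_with <- function(res, k_rem) {
    if (all(res == 0)) return(TRUE)
    if (k_rem == 0L) return(FALSE)
    key <- paste(c(res, k_rem), collapse = ",")
    if (!is.null(failed[[key]])) return(FALSE)
    e_star <- which(res > 0)[1]
    cands <- enumerate_elements(net, idx, res, e_star, variant)
    for (u in cands) {
      used <- u > 0
      wmax <- min(floor(res[used] / u[used]))
      if (wmax < 1) next
      for (wt in wmax:1) {
        if (feasible_with(res - wt * u, k_rem - 1L)) return(TRUE)
      }
    }
    failed[[key]] <- TRUE
    FALSE
  }

  for (k in seq_len(k_cap)) {
    if (feasible_with(f, as.integer(k))) return(as.integer(k))
  }
  Inf
}

## Enumerate candidate element usage vectors that (a) respect the residual
## capacities, (b) use edge e_star at least once, and (c) are admissible for
## the variant. Paths/cycles are enumerated by simple DFS; trails and walks
## by a search over (node, usage) states so that each usage multiset is
## produced once.
enumerate_elements <- function(net, idx, res, e_star, variant) {
  if (variant == "fdpc") {
    c(enum_simple_paths(net, idx, res, e_star),
      enum_simple_cycles(net, idx, res, e_star))
  } else {
    cap <- if (variant == "fdt") pmin(res, 1) else res
    enum_state_walks(net, idx, cap, e_star)
  }
}

enum_simple_paths <- function(net, idx, res, e_star) {
  out <- list()
  m <- net$m
  walk <- function(v, visited, usage) {
    if (v == idx$t) {
      if (usage[e_star] > 0) out[[length(out) + 1L]] <<- usage
      return(invisible(NULL))
    }
    for (e in idx$out_e[[v]]) {
      if (res[e] == 0) next
      w <- idx$ei_to[e]
      if (visited[w]) next
      visited[w] <- TRUE
      usage[e] <- 1
      walk(w, visited, usage)
      visited[w] <- FALSE
      usage[e] <- 0
    }
  }
  visited <- logical(net$n)
  visited[idx$s] <- TRUE
  walk(idx$s, visited, numeric(m))
  out
}

enum_simple_cycles <- function(net, idx, res, e_star) {
  if (res[e_star] == 0) return(list())
  out <- list()
  u0 <- idx$ei_from[e_star]
  v0 <- idx$ei_to[e_star]
  ## simple paths v0 -> u0 avoiding repeats, then close with e_star
  walk <- function(v, visited, usage) {
    if (v == u0) {
      usage[e_star] <- 1
      out[[length(out) + 1L]] <<- usage
      return(invisible(NULL))
    }
    for (e in idx$out_e[[v]]) {
      if (res[e] == 0 || e == e_star) next
      w <- idx$ei_to[e]
      if (visited[w]) next
      visited[w] <- TRUE
      usage[e] <- 1
      walk(w, visited, usage)
      visited[w] <- FALSE
      usage[e] <- 0
    }
  }
  if (u0 == v0) return(list())  # self-loops are rejected at load anyway
  visited <- logical(net$n)
  visited[v0] <- TRUE
  visited[idx$s] <- TRUE  # cycles never contain the source
  if (idx$t != v0) visited[idx$t] <- TRUE  # nor the sink
  walk(v0, visited, numeric(net$m))
  out
}

enum_state_walks <- function(net, idx, cap, e_star) {
  out <- list()
  seen_out <- new.env(parent = emptyenv())
  seen_state <- new.env(parent = emptyenv())
  step <- function(v, usage) {
    key <- paste(c(v, usage), collapse = ",")
    if (!is.null(seen_state[[key]])) return(invisible(NULL))
    seen_state[[key]] <- TRUE
    if (v == idx$t && usage[e_star] > 0) {
      ukey <- paste(usage, collapse = ",")
      if (is.null(seen_out[[ukey]])) {
        seen_out[[ukey]] <- TRUE
        out[[length(out) + 1L]] <<- usage
      }
    }
    for (e in idx$out_e[[v]]) {
      if (usage[e] >= cap[e]) next
      usage[e] <- usage[e] + 1
      step(idx$ei_to[e], usage)
      usage[e] <- usage[e] - 1
    }
  }
  step(idx$s, numeric(net$m))
  out
}
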