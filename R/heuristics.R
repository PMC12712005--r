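#' Greedy residual-graph decomposition into paths and cycles
#'
#' The two Dijkstra-variant baselines: repeatedly extract an s-t path from
#' the residual flow graph — chosen by fewest edges (`rule = "shortest"`)
#' or by maximum bottleneck (`rule = "widest"`) — with weight equal to its
#' bottleneck residual, subtract it, and once no s-t path remains extract
#' cycles from the leftover circulation the same way. Every iteration
#' zeroes at least one residual edge, so the result has at most `m`
#' elements; its size is an upper bound on the exact paths-or-cycles
#' minimum. Ties are broken deterministically by lexicographic node order;
#' cycles are taken after all s-t paths, so the residual stays a valid
#' circulation throughout.
#'
#' @param net A [flow_network()].
#' @param rule `"shortest"` or `"widest"`.
#' @return A decomposition tibble (paths and cycles, exact flow fit).
#' @export
greedy_decompose <- function(net, rule = c("shortest", "widest")) {
  rule <- match.arg(rule)
  idx <- net_index(net)
  res <- net$edges$flow
  elements <- list()
  weights <- numeric(0)
  push <- function(edges_path) {
    w <- min(res[edges_path])
    res[edges_path] <<- res[edges_path] - w
    nodes_seq <- c(net$nodes[idx$ei_from[edges_path[1]]],
                   net$nodes[idx$ei_to[edges_path]])
    elements[[length(elements) + 1L]] <<- nodes_seq
    weights <<- c(weights, w)
  }
  ## phase 1: s-t paths
  repeat {
    p <- residual_path(net, idx, res, rule)
    if (is.null(p)) break
    push(p)
  }
  ## phase 2: cycles in the leftover circulation
  repeat {
    vs <- which(vapply(seq_len(net$n), function(v) {
      any(res[idx$out_e[[v]]] > 0)
    }, logical(1)))
    if (length(vs) == 0) break
    v0 <- vs[order(net$nodes[vs])][1]
    cyc <- residual_cycle(net, idx, res, v0, rule)
    if (is.null(cyc)) {
      rlang::abort("residual circulation has no cycle; invalid network?")
    }
    push(cyc)
  }
  decomposition(net, elements, weights)
}

## best s-t path in the residual graph under the rule, as a vector of edge
## indices, or NULL if t is unreachable
residual_path <- function(net, idx, res, rule) {
  best <- best_routes(net, idx, res, idx$s, rule)
  if (is.na(best$parent_edge[idx$t]) && idx$t != idx$s) return(NULL)
  trace_back(best$parent_edge, idx, idx$t)
}

## best cycle through v0 in the residual graph: best route v0 -> u plus a
## closing residual edge (u, v0)
residual_cycle <- function(net, idx, res, v0, rule) {
  best <- best_routes(net, idx, res, v0, rule)
  close_edges <- idx$in_e[[v0]]
  close_edges <- close_edges[res[close_edges] > 0]
  if (length(close_edges) == 0) return(NULL)
  cand <- NULL
  cand_score <- NULL
  for (e in close_edges) {
    u <- idx$ei_from[e]
    reachable <- (u == v0) || !is.na(best$parent_edge[u])
    if (!reachable) next
    score <- if (rule == "shortest") {
      best$dist[u] + 1
    } else {
      -min(best$width[u], res[e])
    }
    if (is.null(cand) || score < cand_score) {
      cand <- e
      cand_score <- score
    }
  }
  if (is.null(cand)) return(NULL)
  u <- idx$ei_from[cand]
  prefix <- if (u == v0) integer(0) else trace_back(best$parent_edge, idx, u)
  c(prefix, cand)
}

## single-source best routes over residual edges: BFS edge counts for
## "shortest", max-bottleneck Dijkstra for "widest"; deterministic
## lexicographic tie-breaking
best_routes <- function(net, idx, res, s0, rule) {
  n <- net$n
  parent_edge <- rep(NA_integer_, n)
  if (rule == "shortest") {
    dist <- rep(Inf, n)
    dist[s0] <- 0
    queue <- c(s0)
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      es <- idx$out_e[[v]]
      es <- es[res[es] > 0]
      es <- es[order(net$nodes[idx$ei_to[es]])]
      for (e in es) {
        wn <- idx$ei_to[e]
        if (is.infinite(dist[wn]) && wn != s0) {
          dist[wn] <- dist[v] + 1
          parent_edge[wn] <- e
          queue <- c(queue, wn)
        }
      }
    }
    list(parent_edge = parent_edge, dist = dist, width = NULL)
  } else {
    width <- rep(0, n)
    width[s0] <- Inf
    done <- logical(n)
    repeat {
      open <- which(!done & width > 0)
      if (length(open) == 0) break
      v <- open[order(-width[open], net$nodes[open])][1]
      done[v] <- TRUE
      es <- idx$out_e[[v]]
      es <- es[res[es] > 0]
      es <- es[order(net$nodes[idx$ei_to[es]])]
      for (e in es) {
        wn <- idx$ei_to[e]
        if (wn == s0) next
        cand <- min(width[v], res[e])
        if (cand > width[wn]) {
          width[wn] <- cand
          parent_edge[wn] <- e
        }
      }
    }
    list(parent_edge = parent_edge, dist = NULL, width = width)
  }
}

trace_back <- function(parent_edge, idx, v) {
  path <- integer(0)
  while (!is.na(parent_edge[v])) {
    e <- parent_edge[v]
    path <- c(e, path)
    v <- idx$ei_from[e]
  }
  path
}
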