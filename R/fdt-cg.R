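#' Create an empty pool of strongly-connected-component cuts
#'
#' The pool holds the components for which the outgoing-edge disjunction
#' has been generated so far, deduplicated by internal edge set. Cuts are
#' valid for every s-t trail regardless of k, so a pool may be shared
#' across the probes of one minimum-k search.
#'
#' @return A `cut_pool` environment.
#' @export
cut_pool <- function() {
  p <- new.env(parent = emptyenv())
  p$components <- list()
  p$keys <- character(0)
  class(p) <- "cut_pool"
  p
}

pool_add <- function(pool, comp) {
  key <- paste(sort(comp$internal_edges), collapse = ",")
  if (key %in% pool$keys) return(invisible(FALSE))
  pool$keys <- c(pool$keys, key)
  pool$components[[length(pool$components) + 1L]] <- comp
  invisible(TRUE)
}

#' Build the k-FDT constraint-generation model for a given cut pool
#'
#' Binary edge variables per element with weak conservation (at most one
#' edge out of the source, balance at internal nodes) or the basic signed
#' form for exactly-k semantics, the flow superposition constraints, and,
#' for every component `C` in the pool and every element, the linearized
#' disjunction "either some internal edge of `C` is unselected, or some
#' edge leaving `C`'s edge set is selected", using a binary selector with
#' big-M value `|C|` (the number of internal edges).
#'
#' @param net A [flow_network()].
#' @param k Number of elements.
#' @param pool A [cut_pool()] (possibly empty).
#' @param exact_k Require exactly `k` nonempty elements.
#' @param symmetry_break Optional weight ordering.
#' @return A `milp_model`.
#' @export
build_fdt_cg <- function(net, k, pool = cut_pool(), exact_k = FALSE,
                         symmetry_break = FALSE) {
  idx <- net_index(net)
  model <- milp_model()
  add_element_blocks(model, net, k, x_integer = FALSE)
  add_flow_superposition(model, net)
  if (symmetry_break) add_symmetry_breaking(model)
  for (i in seq_len(k)) {
    if (exact_k) {
      add_signed_conservation(model, net, idx, i)
    } else {
      add_weak_conservation(model, net, idx, i)
    }
  }
  for (comp in pool$components) {
    Csz <- length(comp$internal_edges)
    M <- Csz
    for (i in seq_len(k)) {
      x <- model$blocks$x[, i]
      beta <- milp_add_vars(model, 1, lb = 0, ub = 1)
      ein <- comp$internal_edges
      eout <- comp$outgoing_edges
      ## beta = 1  <=>  all internal edges selected
      milp_add_constraint(model, c(x[ein], beta),
                          c(rep(1, length(ein)), -M), lo = Csz - M)
      milp_add_constraint(model, c(x[ein], beta),
                          c(rep(1, length(ein)), -M), hi = Csz - 1)
      ## if beta = 1, select an edge leaving the component's edge set
      milp_add_constraint(model, c(x[eout], beta),
                          c(rep(1, length(eout)), -1), lo = 0)
    }
  }
  model$net <- net
  model$variant <- "fdt"
  model
}

#' Find strongly connected components violating the trail condition
#'
#' For each element's selected edge set, adds the auxiliary edge `(t, s)`
#' and computes strongly connected components of the resulting subgraph
#' (restricted to incident nodes plus `s` and `t`). Every component with at
#' least one selected internal edge that is not the component containing
#' the source violates the outgoing-edge condition and is returned as a
#' cut. An empty result certifies that every element's support can be
#' ordered into an s-t trail (or is empty).
#'
#' @param net A [flow_network()].
#' @param supports A list of integer vectors of selected edge indices, one
#'   per element.
#' @return A list of components, each a list with `nodes`,
#'   `internal_edges` (indices into `net$edges`) and `outgoing_edges`
#'   (indices of all edges of the network leaving the component's node set,
#'   minus the internal ones).
#' @export
find_violating_components <- function(net, supports) {
  out <- list()
  seen <- character(0)
  for (sel in supports) {
    if (length(sel) == 0) next
    sub <- net$edges[sel, c("from", "to")]
    sub <- dplyr::bind_rows(sub, tibble::tibble(from = net$sink, to = net$source))
    vn <- unique(c(sub$from, sub$to))
    g <- igraph::graph_from_data_frame(sub, vertices = vn)
    comp <- igraph::components(g, mode = "strong")
    memb <- comp$membership
    s_comp <- memb[[net$source]]
    for (ci in seq_len(comp$no)) {
      if (ci == s_comp) next
      cn <- names(memb)[memb == ci]
      internal <- sel[net$edges$from[sel] %in% cn & net$edges$to[sel] %in% cn]
      if (length(internal) == 0) next
      key <- paste(sort(internal), collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      outgoing <- setdiff(which(net$edges$from %in% cn), internal)
      out[[length(out) + 1L]] <- list(
        nodes = cn,
        internal_edges = internal,
        outgoing_edges = outgoing
      )
    }
  }
  out
}

#' Solve k-FDT by constraint generation
#'
#' The iterative loop: solve the current model; if infeasible, report
#' infeasible; if feasible and no element's support induces an isolated
#' strongly connected component, order every support into an s-t trail and
#' report it; otherwise add the violating components as cuts and repeat.
#' Terminates because the number of distinct component edge sets is finite.
#'
#' @param net A [flow_network()].
#' @param k Number of elements.
#' @param pool A [cut_pool()] carried across calls (cuts are valid for any
#'   k); a fresh pool is used when `NULL`.
#' @param exact_k Require exactly `k` nonempty elements.
#' @param time_limit Per-solve time limit in seconds.
#' @param max_iterations Safety cap on generation rounds.
#' @return A list with `status`, `decomposition` (when feasible) and
#'   `iterations` (number of ILP solves).
#' @export
solve_fdt_cg <- function(net, k, pool = NULL, exact_k = FALSE,
                         time_limit = Inf, max_iterations = 1000L, ...) {
  if (is.null(pool)) pool <- cut_pool()
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    if (iterations > max_iterations) {
      rlang::abort("constraint generation exceeded max_iterations")
    }
    model <- build_fdt_cg(net, k, pool = pool, exact_k = exact_k, ...)
    sol <- milp_solve(model, time_limit = time_limit)
    if (sol$status != "feasible") {
      return(list(status = sol$status, decomposition = NULL,
                  iterations = iterations))
    }
    supports <- lapply(seq_len(k), function(i) {
      which(sol$values[model$blocks$x[, i]] == 1)
    })
    viol <- find_violating_components(net, supports)
    if (length(viol) == 0) {
      dec <- extract_trail_solution(net, model, sol$values, supports)
      return(list(status = "feasible", decomposition = dec,
                  iterations = iterations))
    }
    for (comp in viol) pool_add(pool, comp)
  }
}

## order each support into an s-t trail by Eulerian splicing and attach
## weights; empty supports are dropped
extract_trail_solution <- function(net, model, values, supports) {
  elements <- list()
  weights <- numeric(0)
  for (i in seq_along(supports)) {
    sel <- supports[[i]]
    if (length(sel) == 0) next
    usage <- numeric(net$m)
    usage[sel] <- 1
    elements[[length(elements) + 1L]] <-
      euler_walk(net, usage, net$source, net$sink)
    weights <- c(weights, values[model$blocks$w[i]])
  }
  decomposition(net, elements, weights)
}

## Hierholzer-style splicing: produce the node sequence of an s-t walk
## using each edge exactly `usage[e]` times. Errors if the multiset does
## not admit such a walk (signals a formulation bug).
euler_walk <- function(net, usage, start, end) {
  idx <- net_index(net)
  remaining <- usage
  total <- sum(usage)
  s <- match(start, net$nodes)
  t <- match(end, net$nodes)
  stack <- c(s)
  out <- integer(0)
  ## deterministic tie-break: try out-edges in order of target node name
  out_order <- lapply(seq_len(net$n), function(v) {
    es <- idx$out_e[[v]]
    es[order(net$nodes[idx$ei_to[es]])]
  })
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    es <- out_order[[v]]
    es <- es[remaining[es] > 0]
    if (length(es) > 0) {
      e <- es[1]
      remaining[e] <- remaining[e] - 1
      stack <- c(stack, idx$ei_to[e])
    } else {
      out <- c(out, v)
      stack <- stack[-length(stack)]
    }
  }
  walk <- rev(out)
  if (length(walk) != total + 1 || walk[1] != s || walk[length(walk)] != t ||
      any(remaining > 0)) {
    rlang::abort("edge multiset admits no s-t walk; formulation bug")
  }
  net$nodes[walk]
}
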