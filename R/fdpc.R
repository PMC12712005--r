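#' Build the k-FDPC model (decomposition into s-t paths or cycles)
#'
#' Each element is modelled by binary edge variables carrying a unit flow,
#' with node-ordering (sequential) constraints adapted to admit exactly one
#' cycle per element: an integer order variable `d[v,i]` and a binary
#' "cycle start" flag `c[v,i]` exist for every internal node, and every
#' edge `(u,v)` between internal nodes imposes
#' `d[v,i] >= d[u,i] + 1 + (n-1)(x[u,v,i] - 1 - c[v,i])`. Per element,
#' `sum_v x[s,v,i] + sum_v c[v,i] <= 1` (or `= 1` for exactly-k
#' semantics): the element is either a single s-t path or a single cycle
#' (or empty). Edges incident to the source or the sink are exempt from the
#' ordering constraint: cycles can never contain `s` or `t`, so ordering is
#' only needed on internal nodes.
#'
#' @param net A [flow_network()].
#' @param k Number of elements (at most, unless `exact_k`).
#' @param exact_k Require exactly `k` nonempty elements.
#' @param degree_cap Include the per-node out-degree cap
#'   `sum_v x[u,v,i] <= 1` (implied by the other constraints but kept by
#'   default as a tightener; disable to test the implication).
#' @param symmetry_break Optional `w_1 <= ... <= w_k` ordering (off by
#'   default; never changes feasibility).
#' @return A `milp_model` whose `blocks` also carry `d` and `c` index
#'   matrices.
#' @export
build_fdpc <- function(net, k, exact_k = FALSE, degree_cap = TRUE,
                       symmetry_break = FALSE) {
  idx <- net_index(net)
  model <- milp_model()
  add_element_blocks(model, net, k, x_integer = FALSE, cycles_allowed = TRUE)
  add_flow_superposition(model, net)
  if (symmetry_break) add_symmetry_breaking(model)
  n <- net$n
  internal <- setdiff(seq_len(n), c(idx$s, idx$t))
  ## order variables d in [1, n] and cycle-start flags for internal nodes
  d <- matrix(NA_integer_, nrow = n, ncol = k)
  cflag <- matrix(NA_integer_, nrow = n, ncol = k)
  for (i in seq_len(k)) {
    d[internal, i] <- milp_add_vars(model, length(internal), lb = 1, ub = n)
    cflag[internal, i] <- milp_add_vars(model, length(internal), lb = 0, ub = 1)
  }
  for (i in seq_len(k)) {
    x <- model$blocks$x[, i]
    if (degree_cap) {
      for (u in seq_len(n)) {
        eout <- idx$out_e[[u]]
        if (length(eout) > 1) {
          milp_add_constraint(model, x[eout], rep(1, length(eout)), hi = 1)
        }
      }
    }
    ## conservation at internal nodes
    for (v in internal) {
      ein <- idx$in_e[[v]]
      eout <- idx$out_e[[v]]
      milp_add_constraint(model, c(x[ein], x[eout]),
                          c(rep(1, length(ein)), rep(-1, length(eout))),
                          lo = 0, hi = 0)
    }
    ## sequential ordering on internal-internal edges:
    ## d_v - d_u - (n-1) x_uv + (n-1) c_v >= 2 - n
    for (e in seq_len(net$m)) {
      u <- idx$ei_from[e]
      v <- idx$ei_to[e]
      if (u == idx$s || v == idx$t) next
      milp_add_constraint(
        model,
        c(d[v, i], d[u, i], x[e], cflag[v, i]),
        c(1, -1, -(n - 1), n - 1),
        lo = 2 - n
      )
    }
    ## one s-t path or one cycle (or neither, unless exact_k)
    s_out <- idx$out_e[[idx$s]]
    ids <- c(x[s_out], cflag[internal, i])
    milp_add_constraint(model, ids, rep(1, length(ids)),
                        lo = if (exact_k) 1 else -Inf, hi = 1)
  }
  model$blocks$d <- d
  model$blocks$c <- cflag
  model$net <- net
  model$variant <- "fdpc"
  model
}

#' Extract the decomposition from a feasible k-FDPC assignment
#'
#' Elements whose edge variables are all zero are dropped (at-most-k
#' semantics). A path element is traversed from the source; a cycle element
#' starts at the flagged cycle-start node (or the first selected node) and
#' follows the unique successors back to the start.
#'
#' @param model The model built by [build_fdpc()].
#' @param values The integral assignment from [milp_solve()].
#' @return A decomposition tibble (see [decomposition()]).
#' @export
extract_fdpc_solution <- function(model, values) {
  net <- model$net
  idx <- net_index(net)
  blocks <- model$blocks
  elements <- list()
  weights <- numeric(0)
  for (i in seq_len(blocks$k)) {
    sel <- which(values[blocks$x[, i]] == 1)
    if (length(sel) == 0) next
    from_s <- any(idx$ei_from[sel] == idx$s)
    if (from_s) {
      start <- idx$s
    } else {
      flagged <- which(!is.na(blocks$c[, i]) & values[blocks$c[, i]] == 1)
      start <- if (length(flagged) >= 1) flagged[1] else idx$ei_from[sel[1]]
    }
    seq_nodes <- follow_support(net, idx, sel, start)
    elements[[length(elements) + 1L]] <- seq_nodes
    weights <- c(weights, values[blocks$w[i]])
  }
  decomposition(net, elements, weights)
}

## follow the unique successor along a selected edge support; returns the
## node-name sequence, erroring if the support is not a single path/cycle
follow_support <- function(net, idx, sel, start) {
  remaining <- sel
  cur <- start
  seq_v <- net$nodes[start]
  repeat {
    nxt <- remaining[idx$ei_from[remaining] == cur]
    if (length(nxt) == 0) break
    if (length(nxt) > 1) {
      rlang::abort("element support has branching; formulation bug")
    }
    cur <- idx$ei_to[nxt]
    seq_v <- c(seq_v, net$nodes[cur])
    remaining <- setdiff(remaining, nxt)
    if (cur == start) break
  }
  if (length(remaining) > 0) {
    rlang::abort("element support is neither a single path nor a single cycle")
  }
  seq_v
}
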