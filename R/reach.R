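#' Build the reachability (spanning-tree) model for k-FDT / k-FDW
#'
#' Each element carries an auxiliary unit flow on integer edge variables
#' (`x` binary for trails, integer in `[0, f_uv]` for walks). On top of the
#' conservation constraints, every node selected by an element must be
#' reachable from the source using selected edges; this is enforced by a
#' spanning tree rooted at the source: binary variables `y[u,v,i]` pick one
#' incoming tree edge per selected node, and integer rank variables
#' `d[v,i]` (with `d[s,i] = 1`, `d[v,i] = 0` for unselected nodes) must
#' strictly increase along tree edges, via the linearized products
#' `phi[u,v,i] = y[u,v,i] * (d[v,i] - d[u,i])` with big-M value `n`.
#'
#' Two formulation modes are available. `"corrected"` (the default)
#' implements the conditional constraints directly:
#' `d_v <= n * sum_in x`, `sum_in x <= B_v * sum_in y` (with `B_v` the
#' in-degree for binary `x`, or the total in-flow for integer `x`),
#' `sum_in y <= 1`, `y <= x`, and `sum_in phi >= sum_in y`.
#' `"literal"` instead uses the printed inequalities
#' `sum_in x >= d_v` and `sum_in x <= sum_in phi` (with `|E| * sum_in y`
#' as the coupling). The literal forms simultaneously cap the rank by the
#' visit count and require ranks to grow along the tree, which is
#' contradictory already on a three-edge path; the mode is kept for study
#' and comparison only.
#'
#' @param net A [flow_network()].
#' @param k Number of elements.
#' @param x_integer `TRUE` for walks (integer multiplicities with
#'   power-of-two product expansion), `FALSE` for trails.
#' @param exact_k Require exactly `k` nonempty elements (basic signed
#'   conservation form).
#' @param formulation_mode `"corrected"` or `"literal"`.
#' @param edge_cap Optional per-edge multiplicity cap (scalar or length-`m`
#'   vector) for walks; defaults to `f_uv`.
#' @param symmetry_break Optional weight ordering.
#' @return A `milp_model` with `d`, `y`, `phi` blocks recorded.
#' @export
build_reach <- function(net, k, x_integer = FALSE, exact_k = FALSE,
                        formulation_mode = c("corrected", "literal"),
                        edge_cap = NULL, symmetry_break = FALSE) {
  formulation_mode <- match.arg(formulation_mode)
  idx <- net_index(net)
  model <- milp_model()
  add_element_blocks(model, net, k, x_integer = x_integer)
  if (x_integer && !is.null(edge_cap)) {
    cap <- pmin(net$edges$flow, rep_len(edge_cap, net$m))
    for (i in seq_len(k)) {
      for (e in seq_len(net$m)) {
        model$ub[model$blocks$x[e, i]] <- cap[e]
      }
    }
  }
  add_flow_superposition(model, net)
  if (symmetry_break) add_symmetry_breaking(model)
  n <- net$n
  m <- net$m
  d <- matrix(NA_integer_, nrow = n, ncol = k)
  y <- matrix(NA_integer_, nrow = m, ncol = k)
  phi <- matrix(NA_integer_, nrow = m, ncol = k)
  for (i in seq_len(k)) {
    if (exact_k) {
      add_signed_conservation(model, net, idx, i)
    } else {
      add_weak_conservation(model, net, idx, i)
    }
    x <- model$blocks$x[, i]
    ## rank variables; d_s fixed to 1
    d[, i] <- milp_add_vars(model, n, lb = 0, ub = n)
    model$lb[d[idx$s, i]] <- 1
    model$ub[d[idx$s, i]] <- 1
    y[, i] <- milp_add_vars(model, m, lb = 0, ub = 1)
    ## y <= x (a tree edge must be selected; for integer x, x >= 1)
    for (e in seq_len(m)) {
      milp_add_constraint(model, c(y[e, i], x[e]), c(1, -1), hi = 0)
    }
    ## phi_uv = y_uv * (d_v - d_u), |d_v - d_u| <= n
    for (e in seq_len(m)) {
      u <- idx$ei_from[e]
      v <- idx$ei_to[e]
      M <- n
      p <- milp_add_vars(model, 1, lb = -n, ub = n)
      milp_add_constraint(model, c(p, y[e, i]), c(1, -M), hi = 0)
      milp_add_constraint(model, c(p, y[e, i]), c(1, M), lo = 0)
      milp_add_constraint(model, c(p, d[v, i], d[u, i], y[e, i]),
                          c(1, -1, 1, M), hi = M)
      milp_add_constraint(model, c(p, d[v, i], d[u, i], y[e, i]),
                          c(1, -1, 1, -M), lo = -M)
      phi[e, i] <- p
    }
    for (v in setdiff(seq_len(n), idx$s)) {
      ein <- idx$in_e[[v]]
      if (length(ein) == 0) next
      nin <- length(ein)
      if (formulation_mode == "corrected") {
        ## d_v = 0 when v is unselected
        milp_add_constraint(model, c(d[v, i], x[ein]),
                            c(1, rep(-n, nin)), hi = 0)
        ## exactly one tree parent for a selected node, none otherwise
        milp_add_constraint(model, y[ein, i], rep(1, nin), hi = 1)
        Bv <- if (x_integer) sum(net$edges$flow[ein]) else nin
        milp_add_constraint(model, c(x[ein], y[ein, i]),
                            c(rep(1, nin), rep(-Bv, nin)), hi = 0)
        ## the tree parent edge must climb: sum phi >= sum y
        milp_add_constraint(model, c(phi[ein, i], y[ein, i]),
                            c(rep(1, nin), rep(-1, nin)), lo = 0)
      } else {
        ## the printed linearizations, kept verbatim for study
        milp_add_constraint(model, c(x[ein], d[v, i]),
                            c(rep(1, nin), -1), lo = 0)      # sum x >= d_v
        milp_add_constraint(model, c(x[ein], phi[ein, i]),
                            c(rep(1, nin), rep(-1, nin)), hi = 0) # sum x <= sum phi
        milp_add_constraint(model, c(x[ein], y[ein, i]),
                            c(rep(1, nin), rep(-m, nin)), hi = 0) # sum x <= |E| sum y
        milp_add_constraint(model, y[ein, i], rep(1, nin), hi = 1)
      }
    }
  }
  model$blocks$d <- d
  model$blocks$y <- y
  model$blocks$phi <- phi
  model$net <- net
  model$variant <- if (x_integer) "fdw" else "fdt"
  model
}

#' Extract the decomposition from a feasible reachability assignment
#'
#' Per element, each edge `(u,v)` is replaced by its multiplicity
#' `x[u,v,i]` parallel copies and an Eulerian s-t walk of the multigraph is
#' spliced together (it exists whenever the model constraints hold). Empty
#' elements are dropped.
#'
#' @param model The model built by [build_reach()].
#' @param values The integral assignment from [milp_solve()].
#' @return A decomposition tibble.
#' @export
extract_reach_solution <- function(model, values) {
  net <- model$net
  blocks <- model$blocks
  elements <- list()
  weights <- numeric(0)
  for (i in seq_len(blocks$k)) {
    usage <- values[blocks$x[, i]]
    if (all(usage == 0)) next
    elements[[length(elements) + 1L]] <-
      euler_walk(net, usage, net$source, net$sink)
    weights <- c(weights, values[blocks$w[i]])
  }
  decomposition(net, elements, weights)
}
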