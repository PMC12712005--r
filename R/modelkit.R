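## Shared MILP building blocks used by all three formulations.
##
## Variable blocks (for k decomposition elements over m edges):
##   x[e, i]  edge-use indicator (binary for paths/cycles and trails) or
##            edge multiplicity (integer in [0, f_e] for walks)
##   w[i]     element weight, integer in [1, Wbar] with
##            Wbar = max over edges (s,v) of f_sv: every nonempty element
##            leaves the source exactly once, so its weight is capped by
##            some source edge flow; empty elements keep w in [1, Wbar]
##            harmlessly because all their products are zero.
##   pi[e, i] the linearized product w_i * x[e, i], integer in [0, f_e].

## weight upper bound: an s-t element leaves the source exactly once, so
## its weight is capped by some source edge flow; a cycle element (FDPC)
## never passes the source, so there the cap is the global max flow
weight_bound <- function(net, cycles_allowed = FALSE) {
  if (cycles_allowed) max(net$edges$flow) else
    max(net$edges$flow[net$edges$from == net$source])
}

#' Add the x/w variable blocks for a k-element decomposition model
#'
#' @param model A [milp_model()].
#' @param net A [flow_network()].
#' @param k Number of elements.
#' @param x_integer If `TRUE`, edge variables are multiplicities in
#'   `[0, f_e]` (walk semantics); otherwise binary.
#' @param cycles_allowed If `TRUE`, the weight bound accounts for cycle
#'   elements that never pass the source (paths-or-cycles variant).
#' @return A list with `x` (an `m x k` matrix of variable indices), `w`
#'   (length-`k` index vector), `Wbar` and `x_integer`; the same list is
#'   stored on the model as `model$blocks`.
#' @export
add_element_blocks <- function(model, net, k, x_integer = FALSE,
                               cycles_allowed = FALSE) {
  m <- net$m
  Wbar <- weight_bound(net, cycles_allowed = cycles_allowed)
  xub <- if (x_integer) rep(net$edges$flow, k) else 1
  x <- matrix(milp_add_vars(model, m * k, lb = 0, ub = xub), nrow = m, ncol = k)
  w <- milp_add_vars(model, k, lb = 1, ub = Wbar)
  blocks <- list(x = x, w = w, Wbar = Wbar, x_integer = x_integer, k = k)
  model$blocks <- blocks
  invisible(blocks)
}

#' Linearize the product of a binary and a bounded integer variable
#'
#' Adds a fresh integer variable `p` constrained to equal
#' `bin * val` on every integral assignment, using the four big-M
#' inequalities with `M = hi` when `lo >= 0`, or `M = max(|lo|, hi)`
#' (the signed variant) when `lo < 0`.
#'
#' @param model A [milp_model()].
#' @param bin Index of a binary variable.
#' @param val Index of an integer variable with known bounds `[lo, hi]`.
#' @param lo,hi Finite bounds of `val`.
#' @return Index of the product variable.
#' @export
linearize_product <- function(model, bin, val, lo, hi) {
  if (!is.finite(lo) || !is.finite(hi)) rlang::abort("`val` must have finite bounds")
  if (lo >= 0) {
    M <- hi
    p <- milp_add_vars(model, 1, lb = 0, ub = hi)
    milp_add_constraint(model, c(p, bin), c(1, -M), hi = 0)        # p <= M bin
    milp_add_constraint(model, c(p, val), c(1, -1), hi = 0)        # p <= val
    milp_add_constraint(model, c(p, val, bin), c(1, -1, -M), lo = -M) # p >= val - M(1-bin)
  } else {
    M <- max(abs(lo), hi)
    p <- milp_add_vars(model, 1, lb = min(lo, 0), ub = max(hi, 0))
    milp_add_constraint(model, c(p, bin), c(1, -M), hi = 0)        # p <=  M bin
    milp_add_constraint(model, c(p, bin), c(1, M), lo = 0)         # p >= -M bin
    milp_add_constraint(model, c(p, val, bin), c(1, -1, M), hi = M)  # p <= val + M(1-bin)
    milp_add_constraint(model, c(p, val, bin), c(1, -1, -M), lo = -M) # p >= val - M(1-bin)
  }
  p
}

#' Expand a bounded integer variable into power-of-two bits
#'
#' Adds binary variables `b_j`, `j = 0..floor(log2(xbar))`, and the
#' constraint `var = sum_j 2^j b_j`. This reduces integer-times-integer
#' products to a sum of binary-times-integer products, each of which
#' [linearize_product()] handles.
#'
#' @param model A [milp_model()].
#' @param var Index of an integer variable in `[0, xbar]`.
#' @param xbar Finite nonnegative upper bound of `var`.
#' @return Integer vector of bit-variable indices (low bit first).
#' @export
expand_power_of_two <- function(model, var, xbar) {
  if (xbar < 0) rlang::abort("`xbar` must be nonnegative")
  nbits <- if (xbar == 0) 1L else floor(log2(xbar)) + 1L
  bits <- milp_add_vars(model, nbits, lb = 0, ub = 1)
  milp_add_constraint(model, c(var, bits), c(1, -(2^(seq_len(nbits) - 1))),
                      lo = 0, hi = 0)
  bits
}

#' Impose the flow superposition constraints
#'
#' For every edge `(u,v)`, requires `sum_i w_i x[e,i] = f_uv`, with each
#' product `w_i x[e,i]` linearized through an auxiliary variable `pi[e,i]`
#' (big-M value `M = f_uv`). For integer edge multiplicities (walks) each
#' `x[e,i]` is first expanded into power-of-two bits and each bit-weight
#' product is linearized individually.
#'
#' @param model A [milp_model()] carrying blocks from [add_element_blocks()].
#' @param net The [flow_network()].
#' @return The model, invisibly; `model$blocks$pi` gains the `m x k` matrix
#'   of product-variable indices.
#' @export
add_flow_superposition <- function(model, net) {
  blocks <- model$blocks
  if (is.null(blocks)) rlang::abort("call add_element_blocks() first")
  k <- blocks$k
  m <- net$m
  f <- net$edges$flow
  Wbar <- blocks$Wbar
  pi_idx <- matrix(milp_add_vars(model, m * k, lb = 0, ub = rep(f, k)),
                   nrow = m, ncol = k)
  for (i in seq_len(k)) {
    w <- blocks$w[i]
    for (e in seq_len(m)) {
      p <- pi_idx[e, i]
      x <- blocks$x[e, i]
      if (!blocks$x_integer) {
        ## pi <= f_uv * x uses M = f_uv; the activation lower bound
        ## pi >= w - (1-x) M needs M >= Wbar, or an element with weight
        ## above f_uv could never leave edge (u,v) unused
        milp_add_constraint(model, c(p, x), c(1, -f[e]), hi = 0)
        milp_add_constraint(model, c(p, w), c(1, -1), hi = 0)
        milp_add_constraint(model, c(p, w, x), c(1, -1, -Wbar), lo = -Wbar)
      } else {
        bits <- expand_power_of_two(model, x, f[e])
        prods <- vapply(bits, function(b) {
          linearize_product(model, b, w, lo = 1, hi = Wbar)
        }, numeric(1))
        ## pi = sum_j 2^j (b_j * w)
        milp_add_constraint(model, c(p, prods),
                            c(1, -(2^(seq_along(prods) - 1))), lo = 0, hi = 0)
      }
    }
  }
  for (e in seq_len(m)) {
    milp_add_constraint(model, pi_idx[e, ], rep(1, k), lo = f[e], hi = f[e])
  }
  model$blocks$pi <- pi_idx
  invisible(model)
}

## optional symmetry breaking: w_1 <= w_2 <= ... <= w_k (never affects
## feasibility: elements of any solution can be reordered by weight)
add_symmetry_breaking <- function(model) {
  w <- model$blocks$w
  k <- length(w)
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      milp_add_constraint(model, c(w[i], w[i + 1]), c(1, -1), hi = 0)
    }
  }
  invisible(model)
}

## weak per-element conservation: at most one edge out of s, balance at
## internal nodes ("at most k" semantics: an all-zero element is allowed)
add_weak_conservation <- function(model, net, idx, i) {
  x <- model$blocks$x[, i]
  s_out <- idx$out_e[[idx$s]]
  milp_add_constraint(model, x[s_out], rep(1, length(s_out)), hi = 1)
  for (v in seq_len(net$n)) {
    if (v == idx$s || v == idx$t) next
    ein <- idx$in_e[[v]]
    eout <- idx$out_e[[v]]
    milp_add_constraint(model, c(x[ein], x[eout]),
                        c(rep(1, length(ein)), rep(-1, length(eout))),
                        lo = 0, hi = 0)
  }
  invisible(model)
}

## signed per-element conservation (the basic form: -1 at s, +1 at t),
## forcing exactly one nonempty element per index ("exactly k" semantics)
add_signed_conservation <- function(model, net, idx, i) {
  x <- model$blocks$x[, i]
  for (v in seq_len(net$n)) {
    ein <- idx$in_e[[v]]
    eout <- idx$out_e[[v]]
    rhs <- if (v == idx$t) 1 else if (v == idx$s) -1 else 0
    milp_add_constraint(model, c(x[ein], x[eout]),
                        c(rep(1, length(ein)), rep(-1, length(eout))),
                        lo = rhs, hi = rhs)
  }
  invisible(model)
}
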