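#' Solve one fixed-k flow decomposition probe
#'
#' Dispatches to the formulation for the requested variant: paths or
#' cycles (`"fdpc"`, the sequential model), trails (`"fdt"`, either the
#' constraint-generation loop or the reachability model) or walks
#' (`"fdw"`, the reachability model with integer multiplicities).
#'
#' @param net A [flow_network()].
#' @param k Number of elements (at-most semantics unless `exact_k`).
#' @param variant One of `"fdpc"`, `"fdt"`, `"fdw"`.
#' @param trail_method `"cg"` (constraint generation) or `"reach"`; only
#'   meaningful for `variant = "fdt"`.
#' @param exact_k Require exactly `k` nonempty elements.
#' @param pool Optional shared [cut_pool()] for `"cg"`.
#' @param time_limit Per-solve time limit in seconds.
#' @param ... Passed to the model builders (e.g. `degree_cap`,
#'   `formulation_mode`, `symmetry_break`, `edge_cap`).
#' @return A list with `status`, `decomposition` and `iterations`.
#' @export
solve_fixed_k <- function(net, k, variant = c("fdpc", "fdt", "fdw"),
                          trail_method = c("cg", "reach"), exact_k = FALSE,
                          pool = NULL, time_limit = Inf, ...) {
  variant <- match.arg(variant)
  trail_method <- match.arg(trail_method)
  if (variant == "fdt" && trail_method == "cg") {
    return(solve_fdt_cg(net, k, pool = pool, exact_k = exact_k,
                        time_limit = time_limit, ...))
  }
  model <- switch(variant,
    fdpc = build_fdpc(net, k, exact_k = exact_k, ...),
    fdt = build_reach(net, k, x_integer = FALSE, exact_k = exact_k, ...),
    fdw = build_reach(net, k, x_integer = TRUE, exact_k = exact_k, ...)
  )
  sol <- milp_solve(model, time_limit = time_limit)
  if (sol$status != "feasible") {
    return(list(status = sol$status, decomposition = NULL, iterations = 1L))
  }
  dec <- if (variant == "fdpc") {
    extract_fdpc_solution(model, sol$values)
  } else {
    extract_reach_solution(model, sol$values)
  }
  list(status = "feasible", decomposition = dec, iterations = 1L)
}

new_mfd_result <- function(net, variant, method, search, status, k, dec,
                           iterations, probes, wallclock) {
  structure(
    list(instance = net$name, variant = variant, method = method,
         search = search, status = status, k = k, decomposition = dec,
         iterations = iterations, probes = probes, wallclock = wallclock),
    class = "mfd_result"
  )
}

#' Minimum-k search by linear increment
#'
#' Probes `k = 1, 2, 3, ...` until the first feasible size. Any flow
#' network decomposes into at most `m` paths or cycles (and hence walks),
#' so the search stops at `k = m`; only the trail variant can come back
#' infeasible at that bound, certifying that no trail decomposition exists.
#'
#' @inheritParams solve_fixed_k
#' @param reuse_pool Share generated cuts across probes (trails with
#'   `"cg"`); cuts are valid for every trail independently of k.
#' @param time_limit Global time budget in seconds; a timeout at any probe
#'   aborts with status `"timeout"` rather than reporting a possibly wrong
#'   minimum.
#' @return An `mfd_result` with the probe history.
#' @export
min_k_linear <- function(net, variant = c("fdpc", "fdt", "fdw"),
                         trail_method = c("cg", "reach"),
                         reuse_pool = TRUE, time_limit = Inf, ...) {
  variant <- match.arg(variant)
  trail_method <- match.arg(trail_method)
  t0 <- Sys.time()
  pool <- if (reuse_pool) cut_pool() else NULL
  probes <- list()
  for (k in seq_len(net$m)) {
    remaining <- remaining_budget(t0, time_limit)
    res <- solve_fixed_k(net, k, variant, trail_method, pool = pool,
                         time_limit = remaining, ...)
    probes[[length(probes) + 1L]] <- tibble::tibble(k = k, status = res$status)
    if (res$status == "timeout") {
      return(new_mfd_result(net, variant, trail_method, "linear", "timeout",
                            NULL, NULL, NULL, dplyr::bind_rows(probes),
                            elapsed(t0)))
    }
    if (res$status == "feasible") {
      return(new_mfd_result(net, variant, trail_method, "linear", "feasible",
                            nrow(res$decomposition), res$decomposition,
                            res$iterations, dplyr::bind_rows(probes),
                            elapsed(t0)))
    }
  }
  new_mfd_result(net, variant, trail_method, "linear", "infeasible", NULL,
                 NULL, NULL, dplyr::bind_rows(probes), elapsed(t0))
}

#' Minimum-k search by doubling then interval refinement
#'
#' Probes `k = 1, 2, 4, 8, ...` (capped at `m`) until the first feasible
#' size `K`; the minimum then lies in the interval `(K/2, K]`, which is
#' scanned linearly (or bisected with `binary_refine = TRUE`; feasibility
#' is monotone in k, so both find the same minimum). Returns the same
#' minimum as [min_k_linear()] on every instance.
#'
#' @inheritParams min_k_linear
#' @param binary_refine Use bisection instead of a linear scan inside the
#'   final interval.
#' @return An `mfd_result` with the probe history.
#' @export
min_k_doubling <- function(net, variant = c("fdpc", "fdt", "fdw"),
                           trail_method = c("cg", "reach"),
                           reuse_pool = TRUE, binary_refine = FALSE,
                           time_limit = Inf, ...) {
  variant <- match.arg(variant)
  trail_method <- match.arg(trail_method)
  t0 <- Sys.time()
  pool <- if (reuse_pool) cut_pool() else NULL
  probes <- list()
  results <- new.env(parent = emptyenv())
  probe <- function(k) {
    res <- solve_fixed_k(net, k, variant, trail_method, pool = pool,
                         time_limit = remaining_budget(t0, time_limit), ...)
    probes[[length(probes) + 1L]] <<- tibble::tibble(k = k, status = res$status)
    results[[as.character(k)]] <- res
    res
  }
  finish <- function(status, res = NULL) {
    new_mfd_result(net, variant, trail_method, "doubling", status,
                   if (!is.null(res)) nrow(res$decomposition) else NULL,
                   res$decomposition, res$iterations,
                   dplyr::bind_rows(probes), elapsed(t0))
  }
  ## doubling phase
  k <- 1L
  lo <- 0L  # largest k known infeasible
  feasible_at <- NULL
  repeat {
    res <- probe(k)
    if (res$status == "timeout") return(finish("timeout"))
    if (res$status == "feasible") {
      feasible_at <- k
      feasible_res <- res
      break
    }
    lo <- k
    if (k >= net$m) return(finish("infeasible"))
    k <- min(2L * k, net$m)
  }
  ## refinement in (lo, feasible_at]
  if (binary_refine) {
    hi <- feasible_at
    while (hi - lo > 1L) {
      mid <- lo + (hi - lo) %/% 2L
      res <- probe(mid)
      if (res$status == "timeout") return(finish("timeout"))
      if (res$status == "feasible") {
        hi <- mid
        feasible_res <- res
      } else {
        lo <- mid
      }
    }
  } else {
    for (kk in seq_len(feasible_at - lo - 1L) + lo) {
      res <- probe(kk)
      if (res$status == "timeout") return(finish("timeout"))
      if (res$status == "feasible") {
        feasible_res <- res
        break
      }
    }
  }
  finish("feasible", feasible_res)
}

#' Minimum flow decomposition of a network
#'
#' The main entry point: finds a minimum flow decomposition of `net` into
#' s-t paths or cycles (`"fdpc"`), s-t trails (`"fdt"`) or s-t walks
#' (`"fdw"`), by repeated fixed-k feasibility probes.
#'
#' @inheritParams min_k_linear
#' @param search `"linear"`, `"doubling"`, or `"fixed"` (single probe at
#'   `k`).
#' @param k Required when `search = "fixed"`.
#' @return An `mfd_result`; see [tidy.mfd_result()] and
#'   [glance.mfd_result()].
#' @examples
#' \donttest{
#' net <- fig2_network()
#' mfd(net, "fdw")   # one walk of weight 1
#' mfd(net, "fdpc")  # a path and a cycle
#' }
#' @export
mfd <- function(net, variant = c("fdpc", "fdt", "fdw"),
                search = c("linear", "doubling", "fixed"), k = NULL,
                trail_method = c("cg", "reach"), time_limit = Inf, ...) {
  variant <- match.arg(variant)
  search <- match.arg(search)
  trail_method <- match.arg(trail_method)
  if (search == "fixed") {
    if (is.null(k)) rlang::abort("`search = \"fixed\"` requires `k`")
    t0 <- Sys.time()
    res <- solve_fixed_k(net, k, variant, trail_method,
                         time_limit = time_limit, ...)
    return(new_mfd_result(
      net, variant, trail_method, "fixed", res$status,
      if (res$status == "feasible") nrow(res$decomposition) else NULL,
      res$decomposition, res$iterations,
      tibble::tibble(k = k, status = res$status), elapsed(t0)
    ))
  }
  fun <- if (search == "linear") min_k_linear else min_k_doubling
  fun(net, variant, trail_method, time_limit = time_limit, ...)
}

remaining_budget <- function(t0, time_limit) {
  if (!is.finite(time_limit)) return(Inf)
  rem <- time_limit - as.numeric(Sys.time() - t0, units = "secs")
  max(rem, 0.01)
}

elapsed <- function(t0) as.numeric(Sys.time() - t0, units = "secs")

#' @export
print.mfd_result <- function(x, ...) {
  cat("<mfd_result> ", x$instance, " [", x$variant, ", ", x$method, "/",
      x$search, "]: ", x$status, sep = "")
  if (!is.null(x$k)) cat(", k =", x$k)
  if (!is.null(x$iterations)) cat(", iterations =", x$iterations)
  cat(sprintf(", %.2fs\n", x$wallclock))
  if (!is.null(x$decomposition)) {
    d <- x$decomposition
    for (i in seq_len(nrow(d))) {
      cat(sprintf("  [%d] %-5s w=%d  %s\n", i, d$class[i], d$weight[i],
                  paste(d$nodes[[i]], collapse = " -> ")))
    }
  }
  invisible(x)
}
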