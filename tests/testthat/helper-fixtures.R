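# Fixtures and shared lazily-computed results used across test files.

`%||%` <- function(x, y) if (is.null(x)) y else x

fig2_text <- "# fig2\n5\ns a 1\na b 2\nb c 2\nc a 2\na t 1\n"

single_edge_net <- function(f = 7) {
  flow_network(tibble::tibble(from = "s", to = "t", flow = f), name = "one")
}

path_net <- function(f = 3) {
  flow_network(
    tibble::tibble(from = c("s", "a", "b"), to = c("a", "b", "t"),
                   flow = rep(f, 3)),
    name = "path3"
  )
}

## valid network containing a 2-cycle b <-> c reachable from s; supports of
## the form {s->a, a->t} + {b->c, c->b} then have an isolated strongly
## connected component
two_cycle_net <- function() {
  flow_network(
    tibble::tibble(
      from = c("s", "a", "b", "c", "c", "a"),
      to = c("a", "b", "c", "b", "a", "t"),
      flow = c(1, 2, 3, 1, 2, 1)
    ),
    name = "twocycle"
  )
}

## five parallel unit paths: the minimum decomposition size is 5 for every
## variant, exercising the doubling schedule 1, 2, 4, 8, then refinement
five_path_net <- function() {
  flow_network(
    tibble::tibble(
      from = c(rbind("s", paste0("a", 1:5))),
      to = c(rbind(paste0("a", 1:5), "t")),
      flow = 1
    ),
    name = "fivepaths"
  )
}

edge_index <- function(net, from, to) {
  which(net$edges$from == from & net$edges$to == to)
}

## ---- shared acceptance suite, computed once per test run ----------------

.suite_cache <- new.env(parent = emptyenv())

acceptance_suite <- function(n_per_variant = 100, seed = 20260927) {
  key <- paste0("suite_", n_per_variant, "_", seed)
  if (is.null(.suite_cache[[key]])) {
    .suite_cache[[key]] <- sim_suite(suite_configs(n_per_variant, seed = seed))
  }
  .suite_cache[[key]]
}

## per-instance solved summary shared by several acceptance blocks
acceptance_results <- function(n_per_variant = 100, seed = 20260927) {
  key <- paste0("results_", n_per_variant, "_", seed)
  if (!is.null(.suite_cache[[key]])) return(.suite_cache[[key]])
  suite <- acceptance_suite(n_per_variant, seed)
  rows <- lapply(seq_along(suite), function(i) {
    inst <- suite[[i]]
    v <- inst$config$variant
    own <- mfd(inst$net, v, search = "linear",
               trail_method = if (v == "fdt") "cg" else "cg")
    fdt_cg <- if (v == "fdt") own else mfd(inst$net, "fdt", trail_method = "cg")
    fdt_reach <- mfd(inst$net, "fdt", trail_method = "reach")
    fdw <- if (v == "fdw") own else mfd(inst$net, "fdw")
    chk <- if (own$status == "feasible") {
      check_decomposition(inst$net, own$decomposition, v)
    } else {
      list(ok = FALSE)
    }
    tibble::tibble(
      i = i,
      variant = v,
      planted_k = inst$config$planted_k,
      m = inst$net$m,
      is_dag = flowdec:::net_is_dag(inst$net),
      oracle_k = brute_force_min_k(inst$net, v),
      own_status = own$status,
      own_k = own$k %||% NA_integer_,
      own_ok = chk$ok,
      fdt_cg_status = fdt_cg$status,
      fdt_cg_k = fdt_cg$k %||% NA_integer_,
      fdt_reach_status = fdt_reach$status,
      fdt_reach_k = fdt_reach$k %||% NA_integer_,
      fdw_k = fdw$k %||% NA_integer_
    )
  })
  .suite_cache[[key]] <- list(suite = suite, summary = dplyr::bind_rows(rows))
  .suite_cache[[key]]
}
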