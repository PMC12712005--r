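#' The worked cyclic example network
#'
#' Five nodes `s, a, b, c, t` with edges/flows `(s,a,1)`, `(a,b,2)`,
#' `(b,c,2)`, `(c,a,2)`, `(a,t,1)`. This network admits a decomposition
#' into one s-t walk of weight 1, a minimum of two paths-or-cycles (the
#' path `s a t` of weight 1 plus the cycle `a b c a` of weight 2) — but no
#' decomposition into s-t trails at all, because every element can use
#' each cycle edge at most once while the total element weight is capped
#' by the source out-flow 1.
#'
#' @return A [flow_network()].
#' @export
fig2_network <- function() {
  flow_network(
    tibble::tibble(
      from = c("s", "a", "b", "c", "a"),
      to = c("a", "b", "c", "a", "t"),
      flow = c(1, 2, 2, 2, 1)
    ),
    name = "fig2"
  )
}

#' Lasso template: a path and a cycle sharing one node
#'
#' Generalizes [fig2_network()]: a path `s -> a -> t` of weight
#' `path_weight` superposed with a cycle through `a` of length `cycle_len`
#' and weight `cycle_weight`. Whenever `cycle_weight > path_weight` the
#' instance admits no trail decomposition (any decomposition has total
#' weight `path_weight`, while covering a cycle edge with single-use
#' elements needs total weight `cycle_weight` across them).
#'
#' @param path_weight Positive integer flow on the s-t path.
#' @param cycle_weight Positive integer flow on the cycle.
#' @param cycle_len Number of cycle edges (>= 2).
#' @return A [flow_network()].
#' @export
lasso_network <- function(path_weight = 1, cycle_weight = 2, cycle_len = 3) {
  stopifnot(cycle_len >= 2)
  cyc <- c("a", paste0("c", seq_len(cycle_len - 1)), "a")
  flow_network(
    tibble::tibble(
      from = c("s", cyc[-length(cyc)], "a"),
      to = c("a", cyc[-1], "t"),
      flow = c(path_weight, rep(cycle_weight, cycle_len), path_weight)
    ),
    name = paste0("lasso_", path_weight, "_", cycle_weight, "_", cycle_len)
  )
}

#' Generate a synthetic cyclic flow network with a planted decomposition
#'
#' Builds `planted_k` elements admissible for the requested variant and
#' returns the network whose flows are exactly their weighted
#' superposition, so the planted decomposition always verifies with zero
#' residual and the true minimum is at most `planted_k`.
#'
#' Construction: internal nodes are split into a path pool (kept in a
#' fixed topological order, so plain paths never create cycles) and a
#' cycle pool. Each element is an s-t path over an increasing subsequence
#' of the path pool; cyclic content is added as detour cycles anchored at
#' a path node and routed through cycle-pool nodes. For `"fdpc"` the
#' cycles are separate elements (anchored at a node of a planted path, so
#' the network stays weakly connected); for `"fdt"` a cycle is spliced
#' once into its path (a trail); for `"fdw"` it is traversed
#' `cycle_repeats` times (a walk with repeated edges).
#'
#' @param variant One of `"fdpc"`, `"fdt"`, `"fdw"`.
#' @param n_path_nodes Number of internal path-pool nodes (>= 1).
#' @param planted_k Number of planted elements.
#' @param w_max Weights are drawn uniformly from `1..w_max`.
#' @param n_cycles Number of planted cycles (elements for `"fdpc"`,
#'   detours otherwise). For `"fdt"`/`"fdw"` at most one detour per
#'   element is spliced in.
#' @param cycle_len Cycle length in edges (2 or 3).
#' @param cycle_repeats Traversals of each detour for `"fdw"` (>= 2 makes
#'   the element a proper walk).
#' @param seed Integer seed; the same seed reproduces the instance
#'   bitwise.
#' @return A list with `net` (a [flow_network()]) and `planted` (a
#'   decomposition tibble).
#' @export
sim_flow_network <- function(variant = c("fdpc", "fdt", "fdw"),
                             n_path_nodes = 3, planted_k = 2, w_max = 3,
                             n_cycles = 1, cycle_len = 2, cycle_repeats = 2,
                             seed = 1) {
  variant <- match.arg(variant)
  stopifnot(n_path_nodes >= 1, planted_k >= 1, w_max >= 1,
            cycle_len %in% c(2, 3))
  resample <- function(x, size = 1) x[sample.int(length(x), size)]
  withr::with_seed(seed, {
    pathpool <- paste0("p", seq_len(n_path_nodes))
    n_paths <- if (variant == "fdpc") max(1L, planted_k - n_cycles) else planted_k
    n_cyc <- if (variant == "fdpc") planted_k - n_paths else
      min(n_cycles, planted_k)
    paths <- lapply(seq_len(n_paths), function(i) {
      len <- resample(seq_len(n_path_nodes))
      mid <- sort(resample(seq_len(n_path_nodes), len))
      c("s", pathpool[mid], "t")
    })
    cyc_id <- 0L
    make_cycle <- function(anchor) {
      cyc_id <<- cyc_id + 1L
      through <- paste0("q", cyc_id, letters[seq_len(cycle_len - 1)])
      c(anchor, through, anchor)
    }
    elements <- paths
    if (variant == "fdpc" && n_cyc > 0) {
      for (j in seq_len(n_cyc)) {
        host <- paths[[resample(seq_len(n_paths))]]
        anchor <- resample(host[-c(1, length(host))])
        elements[[length(elements) + 1L]] <- make_cycle(anchor)
      }
    }
    if (variant %in% c("fdt", "fdw") && n_cyc > 0) {
      targets <- resample(seq_len(n_paths), n_cyc)
      reps <- if (variant == "fdw") cycle_repeats else 1L
      for (j in seq_len(n_cyc)) {
        host <- elements[[targets[j]]]
        pos <- resample(seq(2, length(host) - 1))
        cyc <- make_cycle(host[pos])
        body <- rep(cyc[-1], reps)
        elements[[targets[j]]] <-
          c(host[seq_len(pos)], body, host[seq(pos + 1, length(host))])
      }
    }
    weights <- sample(seq_len(w_max), length(elements), replace = TRUE)
    build_planted(elements, weights, variant)
  })
}

## superpose weighted elements into a network + planted decomposition
build_planted <- function(elements, weights, variant,
                          name = paste0("synth_", variant)) {
  usage <- list()
  for (i in seq_along(elements)) {
    ns <- elements[[i]]
    for (j in seq_len(length(ns) - 1)) {
      key <- paste(ns[j], ns[j + 1])
      usage[[key]] <- (usage[[key]] %||% 0) + weights[i]
    }
  }
  keys <- names(usage)
  parts <- strsplit(keys, " ", fixed = TRUE)
  edges <- tibble::tibble(
    from = vapply(parts, `[`, character(1), 1),
    to = vapply(parts, `[`, character(1), 2),
    flow = unlist(usage, use.names = FALSE)
  )
  net <- flow_network(edges, name = name)
  list(net = net, planted = decomposition(net, elements, weights))
}

#' Generate a deterministic suite of synthetic instances
#'
#' @param configs A data frame with one row per instance; columns are
#'   arguments of [sim_flow_network()] (missing columns take the
#'   defaults). A `seed` column is required.
#' @return A list of `list(net, planted, config)` in row order.
#' @export
sim_suite <- function(configs) {
  configs <- tibble::as_tibble(configs)
  stopifnot("seed" %in% names(configs))
  lapply(seq_len(nrow(configs)), function(i) {
    args <- as.list(configs[i, , drop = FALSE])
    out <- do.call(sim_flow_network, args)
    out$config <- configs[i, , drop = FALSE]
    out
  })
}

#' Default suite configuration for oracle-checkable instances
#'
#' A mix of variants, planted sizes 1-3, cyclic content and weights chosen
#' so that every instance stays within the brute-force oracle guard
#' (at most 10 edges, flows at most 8).
#'
#' @param n_per_variant Instances per variant.
#' @param seed Base seed; instance i of variant v uses a distinct derived
#'   seed.
#' @return A config tibble for [sim_suite()].
#' @export
suite_configs <- function(n_per_variant = 100, seed = 1) {
  variants <- c("fdpc", "fdt", "fdw")
  cfg <- list()
  for (vi in seq_along(variants)) {
    v <- variants[vi]
    for (i in seq_len(n_per_variant)) {
      ## derived seeds must stay below .Machine$integer.max
      s <- as.integer((as.numeric(seed) * 100003 + vi * 10007 + i) %%
                        2147483629)
      k <- 1L + (i %% 3L)
      ## sizes keep every instance inside the oracle guard:
      ## at most 10 edges and flows at most 8
      cfg[[length(cfg) + 1L]] <- tibble::tibble(
        variant = v,
        n_path_nodes = if (k == 1L) 3L else 2L,
        planted_k = k,
        w_max = if (v == "fdw") max(1L, 4L %/% k) else max(1L, 6L %/% k),
        n_cycles = i %% 2L,
        cycle_len = 2L + (i %% 2L),
        cycle_repeats = 2L,
        seed = s
      )
    }
  }
  dplyr::bind_rows(cfg)
}
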