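test_that("the worked example admits no trail decomposition for any k <= m", {
  net <- fig2_network()
  r <- mfd(net, "fdt", trail_method = "cg")
  expect_equal(r$status, "infeasible")
  expect_equal(r$probes$k, 1:5)
  expect_true(all(r$probes$status == "infeasible"))
})

test_that("violating components are exactly the isolated SCCs", {
  tc <- two_cycle_net()
  sel <- c(edge_index(tc, "s", "a"), edge_index(tc, "a", "t"),
           edge_index(tc, "b", "c"), edge_index(tc, "c", "b"))
  viol <- find_violating_components(tc, list(sel))
  expect_length(viol, 1)
  expect_setequal(viol[[1]]$nodes, c("b", "c"))
  expect_setequal(viol[[1]]$internal_edges,
                  c(edge_index(tc, "b", "c"), edge_index(tc, "c", "b")))
  ## every network edge leaving {b, c} outside the component's edge set
  expect_true(edge_index(tc, "c", "a") %in% viol[[1]]$outgoing_edges)

  ## the full worked-example support orders into a trail: no violation
  expect_length(find_violating_components(fig2_network(), list(1:5)), 0)
  expect_length(find_violating_components(fig2_network(), list(integer(0))), 0)
})

test_that("generated cuts are satisfied by every true trail", {
  ## cut validity (forward direction of the escape-edge condition): any
  ## edge set that orders into an s-t trail either misses an internal edge
  ## of the component or selects one of its outgoing edges
  tc <- two_cycle_net()
  sel <- c(edge_index(tc, "s", "a"), edge_index(tc, "a", "t"),
           edge_index(tc, "b", "c"), edge_index(tc, "c", "b"))
  comp <- find_violating_components(tc, list(sel))[[1]]
  trails <- list(
    c(edge_index(tc, "s", "a"), edge_index(tc, "a", "t")),
    c(edge_index(tc, "s", "a"), edge_index(tc, "a", "b"),
      edge_index(tc, "b", "c"), edge_index(tc, "c", "a"),
      edge_index(tc, "a", "t"))
  )
  for (tr in trails) {
    expect_true(is_trail_set(tc, tr))
    misses_internal <- length(setdiff(comp$internal_edges, tr)) > 0
    uses_outgoing <- length(intersect(comp$outgoing_edges, tr)) > 0
    expect_true(misses_internal || uses_outgoing)
  }
})

test_that("constraint generation terminates with admissible trails", {
  for (inst in Filter(function(x) x$config$variant == "fdt",
                      acceptance_suite(6, seed = 13))) {
    r <- mfd(inst$net, "fdt", trail_method = "cg")
    expect_equal(r$status, "feasible")
    expect_true(all(r$decomposition$class %in% c("path", "trail")))
    expect_true(check_decomposition(inst$net, r$decomposition, "fdt")$ok)
    expect_gte(r$iterations, 1)
    expect_lte(r$iterations, 100)
  }
})

test_that("DAG instances solve in a single generation round", {
  dag <- Filter(function(x) flowdec:::net_is_dag(x$net),
                acceptance_suite(6, seed = 17))
  expect_gte(length(dag), 2)
  for (inst in head(dag, 3)) {
    r <- mfd(inst$net, "fdt", trail_method = "cg")
    expect_equal(r$status, "feasible")
    expect_equal(r$iterations, 1)
  }
})

test_that("sharing the cut pool across k does not change the minimum", {
  insts <- Filter(function(x) x$config$variant == "fdt",
                  acceptance_suite(6, seed = 19))
  for (inst in head(insts, 4)) {
    shared <- min_k_linear(inst$net, "fdt", trail_method = "cg",
                           reuse_pool = TRUE)
    fresh <- min_k_linear(inst$net, "fdt", trail_method = "cg",
                          reuse_pool = FALSE)
    expect_equal(shared$status, fresh$status)
    expect_equal(shared$k, fresh$k)
  }
  ## and on a trail-infeasible lasso
  las <- lasso_network(1, 3, 2)
  expect_equal(min_k_linear(las, "fdt", reuse_pool = TRUE)$status, "infeasible")
  expect_equal(min_k_linear(las, "fdt", reuse_pool = FALSE)$status, "infeasible")
})

test_that("exactly-k trails use the basic signed conservation form", {
  net <- path_net(3)  # single path, flows 3
  r1 <- mfd(net, "fdt", search = "fixed", k = 1, exact_k = TRUE)
  expect_equal(r1$status, "feasible")
  expect_equal(nrow(r1$decomposition), 1)
  ## two nonempty trails cannot fit a flow whose source edge has flow 3
  ## unless weights split 3 = w1 + w2 over the same path: feasible
  r2 <- mfd(net, "fdt", search = "fixed", k = 2, exact_k = TRUE)
  expect_equal(r2$status, "feasible")
  expect_equal(nrow(r2$decomposition), 2)
  expect_equal(sum(r2$decomposition$weight), 3)
})
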