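test_that("the worked example parses with the printed flow values", {
  nets <- read_flow_graphs(text = fig2_text)
  expect_length(nets, 1)
  net <- nets[[1]]
  expect_s3_class(net, "flow_network")
  expect_equal(net$name, "fig2")
  expect_equal(net$n, 5)
  expect_equal(net$m, 5)
  expect_equal(net$source, "s")
  expect_equal(net$sink, "t")
  expect_equal(net$edges$flow, c(1, 2, 2, 2, 1))
  expect_identical(net$edges, fig2_network()$edges)
})

test_that("smallest legal instance and multi-instance files parse", {
  nets <- read_flow_graphs(text = "# one\n2\ns t 7\n")
  expect_length(nets, 1)
  expect_equal(nets[[1]]$edges$flow, 7)
  expect_equal(nets[[1]]$source, "s")
  expect_equal(nets[[1]]$sink, "t")

  two <- read_flow_graphs(text = paste0("# one\n2\ns t 7\n", fig2_text))
  expect_length(two, 2)
  expect_equal(vapply(two, function(x) x$name, ""), c("one", "fig2"))
})

test_that("write then read is the identity on valid networks", {
  nets <- list(fig2_network(), single_edge_net(), two_cycle_net())
  txt <- write_flow_graphs(nets)
  expect_match(txt, "^# fig2\n5\n")
  back <- read_flow_graphs(text = txt)
  expect_length(back, length(nets))
  for (i in seq_along(nets)) {
    expect_identical(back[[i]]$edges, nets[[i]]$edges)
    expect_identical(back[[i]]$nodes, nets[[i]]$nodes)
    expect_identical(back[[i]]$name, nets[[i]]$name)
  }
  expect_equal(write_flow_graphs(list()), "")
})

test_that("malformed input is rejected in strict mode", {
  expect_error(read_flow_graphs(text = "# bad\n2\ns t x\n"), "non-integer")
  expect_error(read_flow_graphs(text = "# bad\n2\ns t 0\n"), ">= 1")
  expect_error(read_flow_graphs(text = "# bad\n2\ns t\n"), "malformed")
  expect_error(read_flow_graphs(text = "# bad\n3\ns t 1\n"), "declared 3")
  expect_error(read_flow_graphs(text = "s t 1\n"), "before any")
  ## duplicate edge lines (no parallel edges)
  expect_error(read_flow_graphs(text = "# bad\n2\ns t 1\ns t 2\n"),
               "duplicate_edge")
})

test_that("validation reports every violated invariant", {
  ok <- validate_flow_network(fig2_network())
  expect_true(ok$ok)
  expect_equal(nrow(ok$violations), 0)

  ## conservation break at a: in 1+2 = 3, out 2+2 = 4
  edges <- fig2_network()$edges
  edges$flow[edges$from == "a" & edges$to == "t"] <- 2
  rep <- validate_flow_network(edges)
  expect_false(rep$ok)
  expect_true("conservation" %in% rep$violations$kind)
  expect_true("a" %in% rep$violations$where)

  ## two sink-like nodes
  rep2 <- validate_flow_network(tibble::tibble(
    from = c("s", "s"), to = c("t1", "t2"), flow = c(1, 1)
  ))
  expect_false(rep2$ok)
  expect_true("multi_sink" %in% rep2$violations$kind)

  ## self loop
  rep3 <- validate_flow_network(tibble::tibble(
    from = c("s", "a"), to = c("a", "a"), flow = c(1, 1)
  ))
  expect_true("self_loop" %in% rep3$violations$kind)

  ## disconnected
  rep4 <- validate_flow_network(tibble::tibble(
    from = c("s", "b"), to = c("t", "c"), flow = c(1, 1)
  ))
  expect_true("disconnected" %in% rep4$violations$kind)
})

test_that("lenient mode returns networks with attached reports", {
  nets <- read_flow_graphs(text = "# bad\n3\ns a 1\na t 2\n", strict = FALSE)
  expect_length(nets, 1)
  rep <- attr(nets[[1]], "validation")
  expect_false(rep$ok)
  expect_true("conservation" %in% rep$violations$kind)
})
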