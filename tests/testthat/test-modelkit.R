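pin <- function(model, idx, val) {
  milp_add_constraint(model, idx, 1, lo = val, hi = val)
}

test_that("binary-times-bounded linearization equals the true product", {
  ## signed case, exhaustive over bin in {0,1}, val in [-3, 3]
  for (b in 0:1) {
    for (v in -3:3) {
      model <- milp_model()
      bin <- milp_add_vars(model, 1, 0, 1)
      val <- milp_add_vars(model, 1, -3, 3)
      p <- linearize_product(model, bin, val, lo = -3, hi = 3)
      pin(model, bin, b)
      pin(model, val, v)
      sol <- milp_solve(model)
      expect_equal(sol$status, "feasible")
      expect_equal(sol$values[p], b * v, info = paste("bin", b, "val", v))
    }
  }
  ## nonnegative case
  for (b in 0:1) {
    for (v in c(0, 4, 10)) {
      model <- milp_model()
      bin <- milp_add_vars(model, 1, 0, 1)
      val <- milp_add_vars(model, 1, 0, 10)
      p <- linearize_product(model, bin, val, lo = 0, hi = 10)
      pin(model, bin, b)
      pin(model, val, v)
      sol <- milp_solve(model)
      expect_equal(sol$values[p], b * v)
    }
  }
})

test_that("power-of-two expansion represents every value in range", {
  cases <- list(list(xbar = 5, nbits = 3), list(xbar = 1, nbits = 1),
                list(xbar = 8, nbits = 4))
  for (cs in cases) {
    model <- milp_model()
    x <- milp_add_vars(model, 1, 0, cs$xbar)
    bits <- expand_power_of_two(model, x, cs$xbar)
    expect_length(bits, cs$nbits)
    for (v in 0:cs$xbar) {
      m2 <- milp_model()
      x2 <- milp_add_vars(m2, 1, 0, cs$xbar)
      b2 <- expand_power_of_two(m2, x2, cs$xbar)
      pin(m2, x2, v)
      sol <- milp_solve(m2)
      expect_equal(sol$status, "feasible")
      expect_equal(sum(sol$values[b2] * 2^(seq_along(b2) - 1)), v)
    }
  }
})

test_that("integer-times-integer products reduce correctly through bits", {
  ## x in [0,5], y in [1,4]: xy via bit expansion + binary products
  for (xv in 0:5) {
    for (yv in 1:4) {
      model <- milp_model()
      x <- milp_add_vars(model, 1, 0, 5)
      y <- milp_add_vars(model, 1, 1, 4)
      bits <- expand_power_of_two(model, x, 5)
      prods <- vapply(bits, function(b) {
        linearize_product(model, b, y, lo = 1, hi = 4)
      }, numeric(1))
      xy <- milp_add_vars(model, 1, 0, 20)
      milp_add_constraint(model, c(xy, prods),
                          c(1, -(2^(seq_along(prods) - 1))), lo = 0, hi = 0)
      pin(model, x, xv)
      pin(model, y, yv)
      sol <- milp_solve(model)
      expect_equal(sol$values[xy], xv * yv)
    }
  }
})

test_that("flow superposition pins the only solution on a single edge", {
  net <- single_edge_net(7)
  model <- milp_model()
  add_element_blocks(model, net, k = 1)
  add_flow_superposition(model, net)
  sol <- milp_solve(model)
  expect_equal(sol$status, "feasible")
  expect_equal(sol$values[model$blocks$x[1, 1]], 1)
  expect_equal(sol$values[model$blocks$w[1]], 7)
})

test_that("one element cannot superpose onto clashing flows", {
  ## fig2 with k = 1 and binary x: w would have to equal both 1 and 2
  net <- fig2_network()
  model <- milp_model()
  add_element_blocks(model, net, k = 1, cycles_allowed = TRUE)
  add_flow_superposition(model, net)
  sol <- milp_solve(model)
  expect_equal(sol$status, "infeasible")
})

test_that("integer edge variables get floor(log2(f)) + 1 bits", {
  net <- single_edge_net(5)
  model <- milp_model()
  add_element_blocks(model, net, k = 1, x_integer = TRUE)
  nv0 <- model$nv
  add_flow_superposition(model, net)
  ## one pi var + 3 bits + 3 bit products for f = 5
  expect_equal(model$nv - nv0, 1 + 3 + 3)
})

test_that("the backend reports trivial feasibility and infeasibility", {
  expect_equal(milp_solve(milp_model())$status, "feasible")
  model <- milp_model()
  x <- milp_add_vars(model, 1, 0, 1)
  milp_add_constraint(model, x, 1, lo = 2)
  expect_equal(milp_solve(model)$status, "infeasible")
})

test_that("symmetry breaking never changes the minimum k", {
  for (inst in head(acceptance_suite(6, seed = 11), 4)) {
    v <- inst$config$variant
    plain <- mfd(inst$net, v)
    model_sb <- mfd(inst$net, v, symmetry_break = TRUE)
    expect_equal(model_sb$status, plain$status)
    expect_equal(model_sb$k, plain$k)
  }
})
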