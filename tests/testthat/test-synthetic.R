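test_that("random network generation is deterministic given a seed and
           respects the requested structure", {
  n1 <- generate_random_network(8, in_degree = 2, n_inputs = 1, seed = 7)
  n2 <- generate_random_network(8, in_degree = 2, n_inputs = 1, seed = 7)
  expect_identical(vapply(n1$rules, deparse, ""),
                   vapply(n2$rules, deparse, ""))
  expect_identical(n1$inputs, n2$inputs)

  n3 <- generate_random_network(10, in_degree = 2, n_inputs = 2, seed = 1)
  expect_length(n3$rules, 8)
  expect_length(n3$inputs, 2)
  expect_error(generate_random_network(4, in_degree = 6), "infeasible")
})

test_that("truth-table rules reference every drawn regulator and are not
           constant", {
  net <- generate_random_network(6, in_degree = 3, seed = 12,
                                 rule_style = "truth_table_dnf")
  for (nm in names(net$rules)) {
    regs <- unique(rule_literals(net$rules[[nm]])$node)
    expect_length(regs, 3)
    # non-constant: both output values occur over the regulators' corners
    vals <- vapply(0:7, function(i) {
      bits <- stats::setNames(as.integer(bitwAnd(i, c(1, 2, 4)) != 0), regs)
      eval_rule(net$rules[[nm]], bits)
    }, 0L)
    expect_true(any(vals == 0L) && any(vals == 1L))
  }
})

test_that("the toy library has its documented dynamics", {
  toys <- toy_library()
  # toggle handled in the engine tests; self-activator: fixed points 0, 1
  self <- enumerate_attractors(toys$self_activator)
  expect_setequal(vapply(self, function(a) a$states[1, 1], 0L), c(0L, 1L))
  # negative ring: synchronous cycles only
  ring <- enumerate_attractors(toys$negative_ring)
  expect_true(all(vapply(ring, `[[`, 0L, "length") > 1))
  # isolated input decays to the unique all-zero fixed point
  iso <- enumerate_attractors(toys$isolated_input)
  expect_length(iso, 1)
  expect_equal(iso[[1]]$basin_fraction, 1)
})

test_that("generated networks keep their discrete fixed points as
           continuous equilibria and their basins exhaust the state
           space", {
  for (seed in c(2, 9, 21)) {
    net <- generate_random_network(9, in_degree = 2, n_inputs = 2,
                                   seed = seed)
    aset <- enumerate_attractors(net)
    expect_equal(sum(vapply(aset, `[[`, 0, "basin_count")), 2^9)
    p <- squad_params(net)
    for (a in Filter(function(a) a$length == 1, aset)) {
      s <- stats::setNames(as.numeric(a$states[, 1]), net$nodes)
      r <- relax(net, p, s)
      expect_true(r$converged)
      expect_equal(unname(r$levels), unname(s), tolerance = 1e-8,
                   info = paste("seed", seed))
    }
  }
})
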