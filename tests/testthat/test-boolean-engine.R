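test_that("synchronous step honours rules, input decay and clamps", {
  net <- bcell_net()
  # Naive and PC patterns are invariant
  naive <- make_state(net, c("Bach2", "Pax5"))
  expect_identical(boolean_step(net, naive), as_boolean_state(net, naive))
  pc <- make_state(net, c("Blimp1", "Irf4", "XBP1"))
  expect_identical(boolean_step(net, pc), as_boolean_state(net, pc))
  # from the all-ones state with Ag clamped: Ag stays, unclamped inputs decay
  ones <- stats::setNames(rep(1, 22), net$nodes)
  nxt <- boolean_step(net, ones, clamps = c(Ag = 1))
  expect_identical(unname(nxt["Ag"]), 1L)
  expect_identical(unname(nxt["IL2"]), 0L)
  expect_identical(unname(nxt["CD40L"]), 0L)
})

test_that("state encoding is bijective with the bit map", {
  net <- toy_library()$negative_ring
  for (code in 0:7)
    expect_equal(encode_state(net, decode_state(net, code)), code)
})

test_that("trajectories terminate on fixed points and synchronous cycles", {
  toggle <- toy_library()$toggle
  fa <- find_attractor(toggle, c(A = 1, B = 0))
  expect_identical(fa$length, 1L)
  expect_identical(fa$transient, 0L)
  expect_identical(fa$states[, 1], c(A = 1L, B = 0L))
  # (0,0) <-> (1,1) under synchronous update
  fa2 <- find_attractor(toggle, c(A = 0, B = 0))
  expect_identical(fa2$length, 2L)
  expect_identical(fa2$transient, 0L)
  expect_identical(sort(apply(fa2$states, 2, paste, collapse = "")),
                   c("00", "11"))
})

test_that("exhaustive enumeration of the toy models matches their hand
           enumeration", {
  toys <- toy_library()
  aset <- enumerate_attractors(toys$toggle)
  expect_length(aset, 3)
  fps <- Filter(function(a) a$length == 1, aset)
  expect_setequal(vapply(fps, function(a) paste(a$states[, 1],
                                                collapse = ""), ""),
                  c("10", "01"))
  cyc <- Filter(function(a) a$length == 2, aset)
  expect_length(cyc, 1)
  expect_equal(cyc[[1]]$basin_count, 2)
  expect_equal(sum(vapply(aset, `[[`, 0, "basin_fraction")), 1)

  self <- enumerate_attractors(toys$self_activator)
  expect_length(self, 2)
  expect_true(all(vapply(self, `[[`, 0L, "length") == 1L))

  ring <- enumerate_attractors(toys$negative_ring)
  expect_true(all(vapply(ring, `[[`, 0L, "length") > 1L))  # no fixed point

  iso <- enumerate_attractors(toys$isolated_input)
  expect_length(iso, 1)
  expect_identical(iso[[1]]$states[, 1], c(A = 0L))
  expect_equal(iso[[1]]$basin_fraction, 1)
})

test_that("bit-parallel enumeration equals the brute-force oracle on random
           networks of both rule styles", {
  for (style in c("and_or_not_tree", "truth_table_dnf")) {
    for (seed in c(11, 22, 33)) {
      net <- generate_random_network(8, in_degree = 2, n_inputs = 2,
                                     rule_style = style, seed = seed)
      expect_matches_oracle(enumerate_attractors(net),
                            oracle_attractors(net))
    }
  }
})

test_that("enumeration under clamps equals the oracle and basins still sum
           to one", {
  net <- generate_random_network(8, in_degree = 2, seed = 5)
  cl <- c(n01 = 1, n05 = 0)
  aset <- enumerate_attractors(net, clamps = cl)
  expect_matches_oracle(aset, oracle_attractors(net, clamps = cl))
  expect_equal(sum(vapply(aset, `[[`, 0, "basin_fraction")), 1)
  expect_identical(attr(aset, "n_states"), 2^6)
  # clamped bits are fixed in every reported state
  for (a in aset) {
    expect_true(all(a$states["n01", ] == 1L))
    expect_true(all(a$states["n05", ] == 0L))
  }
})

test_that("the enumeration guard refuses oversized state spaces", {
  net <- generate_random_network(10, in_degree = 2, seed = 1)
  expect_error(enumerate_attractors(net, max_free = 8), "refused")
})

test_that("trajectories from antigen-stimulated states reach one of the
           four wild-type fixed points", {
  net <- bcell_net()
  wt_keys <- vapply(wt_attractors(), function(a)
    paste(a$states[, 1], collapse = ""), "")
  s <- make_state(net, "Ag")
  fa <- find_attractor(net, s)
  expect_identical(fa$length, 1L)
  expect_true(paste(fa$states[, 1], collapse = "") %in% wt_keys)
  # a few random initial states with Ag on
  set.seed(1)
  for (i in 1:5) {
    s <- stats::setNames(rbinom(22, 1, 0.5), net$nodes)
    s["Ag"] <- 1
    fa <- find_attractor(net, s)
    expect_true(paste(fa$states[, 1], collapse = "") %in% wt_keys)
  }
})

test_that("mutant enumeration fixes the clamped bit everywhere", {
  net <- bcell_net()
  aset <- mutant_attractors(net, "Blimp1", 1)
  expect_length(aset, 1)
  expect_true(all(aset[[1]]$states["Blimp1", ] == 1L))
  expect_identical(attr(aset, "n_states"), 2^21)
})
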