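test_that("the sigmoid anchors 0, 0.5, 1 hold to machine precision for all
           gains and the curve is monotone", {
  for (h in c(1, 4, 8, 50, 100)) {
    expect_identical(sigmoid_activation(c(0, 0.5, 1), h), c(0, 0.5, 1))
    grid <- seq(0, 1, by = 1 / 256)
    expect_true(all(diff(sigmoid_activation(grid, h)) >= 0))
  }
  # near step-like behaviour at h = 50
  expect_lt(sigmoid_activation(0.45, 50), 0.08)
  expect_gt(sigmoid_activation(0.55, 50), 0.92)
  # overflow-free for extreme gains
  expect_true(all(is.finite(sigmoid_activation(seq(0, 1, 0.1), 5000))))
  expect_error(sigmoid_activation(0.5, 0), "h must be > 0")
})

test_that("squad_params validates gains and decay rates", {
  net <- bcell_net()
  p <- squad_params(net, h = 50, gamma = 1)
  expect_identical(unname(p$h["Bcl6"]), 50)
  expect_error(squad_params(net, h = -1), "> 0")
  expect_error(squad_params(net, gamma = c(Zz = 1)), "unknown node")
  p2 <- squad_params(net, h = c(stats::setNames(rep(50, 22), net$nodes)))
  expect_identical(p2$h, p$h)
})

test_that("every binary wild-type fixed point is an exact equilibrium of
           the continuous system", {
  net <- bcell_net()
  p <- bcell_params()
  sig <- cell_type_signatures()
  for (lb in rownames(sig)) {
    s <- make_state(net, colnames(sig)[sig[lb, ] == 1])
    expect_equal(max(abs(continuous_derivative(net, p, s))), 0, info = lb)
  }
})

test_that("input nodes decay and clamped nodes have zero rate", {
  net <- bcell_net()
  p <- bcell_params()
  s <- make_state(net)
  s["Ag"] <- 0.8
  d <- continuous_derivative(net, p, s)
  expect_equal(unname(d["Ag"]), -0.8)
  d2 <- continuous_derivative(net, p, s, clamps = c(Ag = 0.8))
  expect_equal(unname(d2["Ag"]), 0)
})

test_that("the three intermediate attractor patterns are equilibria for
           every tested gain", {
  net <- bcell_net()
  pats <- list(
    New1 = c(Bach2 = 1, Pax5 = 1, Bcl6 = 0.5),
    New2 = c(Bach2 = 1, Pax5 = 1, Irf4 = 0.5),
    New3 = c(Bach2 = 1, Pax5 = 1, Bcl6 = 0.5, Irf4 = 0.5))
  for (h in c(1, 4, 8, 50, 100)) {
    p <- squad_params(net, h = h)
    for (nm in names(pats)) {
      s <- make_state(net, pats[[nm]])
      expect_equal(max(abs(continuous_derivative(net, p, s))), 0,
                   info = paste(nm, "h =", h))
    }
  }
})

test_that("relaxation converges to fixed points and respects clamps", {
  net <- bcell_net()
  p <- bcell_params()
  gc <- relax(net, p, make_state(net, c("Bach2", "Bcl6", "Pax5")))
  expect_true(gc$converged)
  expect_equal(unname(gc$levels["Bcl6"]), 1)
  expect_lt(gc$residual, p$convergence_tol)
  # the all-off state drains to the Naive attractor (Pax5 switches on in
  # the absence of Irf4)
  origin <- relax(net, p, make_state(net))
  expect_identical(label_attractor(origin), "Naive")
  # clamp semantics
  r <- relax(net, p, make_state(net), clamps = c(Blimp1 = 1))
  expect_equal(unname(r$levels["Blimp1"]), 1)
  expect_identical(label_attractor(r, clamped = "Blimp1"), "PC")
})

test_that("the steady state of a constant-input node is f(omega)/gamma", {
  # decoupled two-node system: A <- I with I clamped
  net <- regulatory_network(list(A = "I"), inputs = "I")
  for (gamma in c(1, 2)) {
    p <- squad_params(net, h = 8, gamma = gamma, convergence_tol = 1e-12)
    r <- relax(net, p, c(A = 0, I = 0), clamps = c(I = 0.7))
    expect_equal(unname(r$levels["A"]),
                 sigmoid_activation(0.7, 8) / gamma, tolerance = 1e-9)
  }
  # saturated input, gamma = 2: level displaced from 1 to exactly 1/2
  p2 <- squad_params(net, h = 50, gamma = 2, convergence_tol = 1e-12)
  r2 <- relax(net, p2, c(A = 1, I = 1), clamps = c(I = 1))
  expect_equal(unname(r2$levels["A"]), 0.5, tolerance = 1e-9)
})

test_that("random-start sampling is reproducible and finds only the four
           binary attractors", {
  net <- bcell_net()
  p <- bcell_params()
  sa1 <- sample_attractors(net, p, n_runs = 60, seed = 99)
  sa2 <- sample_attractors(net, p, n_runs = 60, seed = 99)
  expect_identical(lapply(sa1, `[[`, "levels"),
                   lapply(sa2, `[[`, "levels"))
  expect_identical(sum(vapply(sa1, `[[`, 0L, "support_count")) +
                     attr(sa1, "n_nonconverged"), 60L)
  labs <- vapply(sa1, label_attractor, "")
  expect_true(all(labs %in% c("Naive", "GC", "Mem", "PC")))
})

test_that("attractor locations move with gamma but binary corners persist
           across the h grid", {
  net <- bcell_net()
  p <- bcell_params()
  sw_h <- parameter_sweep(net, p, "h", grid = c(1, 4, 8, 50, 100))
  gcl <- sw_h[sw_h$start == "GC" & sw_h$node == "Bcl6", ]
  expect_true(all(abs(gcl$level - 1) < 1e-6))
  sw_g <- parameter_sweep(net, p, "gamma", grid = c(1, 2))
  # Pax5's input stays saturated from the GC start, so its steady level is
  # displaced from 1 to f(1)/gamma = 1/2; Bcl6 collapses entirely once its
  # own input falls below threshold
  g2 <- sw_g[sw_g$value == 2 & sw_g$start == "GC", ]
  expect_equal(g2$level[g2$node == "Pax5"], 0.5, tolerance = 1e-6)
  expect_lt(g2$level[g2$node == "Bcl6"], 0.1)
})

test_that("discrete fixed points of arbitrary synthetic networks are
           continuous equilibria at h = 50", {
  for (seed in c(3, 14)) {
    net <- generate_random_network(7, in_degree = 2, n_inputs = 1,
                                   seed = seed)
    p <- squad_params(net)
    aset <- enumerate_attractors(net)
    for (a in Filter(function(a) a$length == 1, aset)) {
      s <- stats::setNames(as.numeric(a$states[, 1]), net$nodes)
      expect_equal(max(abs(continuous_derivative(net, p, s))), 0,
                   info = paste("seed", seed))
    }
  }
})
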