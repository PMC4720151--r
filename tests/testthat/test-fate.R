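test_that("core patterns map to the published cell-type labels", {
  lab <- function(v) label_attractor(stats::setNames(v, bcell_core_nodes))
  expect_identical(lab(c(1, 0, 0, 0, 1, 0)), "Naive")
  expect_identical(lab(c(1, 1, 0, 0, 1, 0)), "GC")
  expect_identical(lab(c(1, 0, 0, 1, 1, 0)), "Mem")
  expect_identical(lab(c(0, 0, 1, 1, 0, 1)), "PC")
  expect_identical(lab(c(0, 0, 0, 1, 0, 0)), "Other")
})

test_that("a clamped core bit yields the -like label when all free bits
           match", {
  s <- stats::setNames(c(0, 0, 0, 0, 1, 0), bcell_core_nodes)
  expect_identical(label_attractor(s, clamped = "Bach2"), "Naive-like")
  # same pattern without the clamp is just Other
  expect_identical(label_attractor(s), "Other")
  s2 <- stats::setNames(c(0, 0, 1, 1, 0, 0), bcell_core_nodes)
  expect_identical(label_attractor(s2, clamped = "XBP1"), "PC-like")
})

test_that("continuous attractors label through their levels", {
  net <- bcell_net()
  p <- bcell_params()
  r <- relax(net, p, make_state(net, c("Bach2", "Irf4", "Pax5")))
  expect_identical(label_attractor(r), "Mem")
})

test_that("an IL4 pulse moves Naive to GC and the pulse machinery respects
           pin-and-release semantics", {
  net <- bcell_net()
  p <- bcell_params()
  naive <- make_state(net, c("Bach2", "Pax5"))
  traj <- simulate_pulses(net, p, naive,
                          pulse_event("IL4", 1, t_on = 5, duration = 10))
  expect_identical(traj$final_label, "GC")
  # IL4 pinned at 1 during the pulse window (the sample at t = 5 itself
  # belongs to the pre-pulse segment)
  idx <- traj$times > 5 & traj$times < 15
  expect_true(all(abs(traj$states[idx, "IL4"] - 1) < 1e-9))
  # IL4 decays after release
  expect_lt(traj$states[length(traj$times), "IL4"], 1e-6)
  # trajectory stays within the unit hypercube (integration tolerance)
  expect_true(all(traj$states > -1e-6 & traj$states < 1 + 1e-6))
})

test_that("pulsing a node at its current level is a no-op", {
  net <- bcell_net()
  p <- bcell_params()
  naive <- make_state(net, c("Bach2", "Pax5"))
  traj <- simulate_pulses(net, p, naive,
                          pulse_event("IL4", 0, t_on = 2, duration = 5))
  expect_identical(traj$final_label, "Naive")
})

test_that("overlapping pulses are rejected", {
  net <- bcell_net()
  p <- bcell_params()
  expect_error(
    simulate_pulses(net, p, make_state(net, c("Bach2", "Pax5")),
                    list(pulse_event("IL4", 1, 5, 10),
                         pulse_event("Ag", 1, 8, 2))),
    "overlapping")
})

test_that("the discrete toggle fate map routes single flips from the fixed
           points onto the synchronous 2-cycle", {
  toggle <- toy_library()$toggle
  fm <- build_fate_map(toggle, engine = "discrete")
  # vertices: (1,0), (0,1) and the 2-cycle
  expect_identical(nrow(fm$vertices), 3L)
  aset <- enumerate_attractors(toggle)
  pat <- vapply(aset, function(a) paste(a$states[, 1], collapse = ""), "")
  i10 <- which(pat == "10")
  icyc <- which(vapply(aset, `[[`, 0L, "length") == 2L)
  # flipping either node of (1,0) yields (0,0) or (1,1), both on the cycle
  from10 <- fm$edges[fm$edges$source == i10, ]
  expect_identical(nrow(from10), 2L)
  expect_true(all(from10$target == icyc))
})

test_that("the discrete mutant report reproduces the hallmark mutant
           phenotypes", {
  net <- bcell_net()
  rep <- mutant_report(net, nodes = c("Blimp1", "Irf4"), engine = "discrete")
  b1 <- rep[rep$node == "Blimp1" & rep$value == 1, ]
  expect_identical(nrow(b1), 1L)             # single attractor
  expect_identical(b1$label, "PC")
  i0 <- rep[rep$node == "Irf4" & rep$value == 0, ]
  expect_setequal(i0$label, c("Naive", "GC"))
  summ <- mutant_summary(rep)
  expect_match(summ$effect[summ$node == "Blimp1" & summ$value == 1],
               "only the PC attractor")
  expect_match(summ$effect[summ$node == "Irf4" & summ$value == 0],
               "loss of Mem, PC")
})

test_that("fate-map out-degree lookups validate their vertex", {
  toggle <- toy_library()$toggle
  fm <- build_fate_map(toggle, engine = "discrete")
  expect_error(fate_map_outdegree(fm, "PC"), "no vertex")
})
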