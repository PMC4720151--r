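test_that("network constructor validates its invariants", {
  expect_error(regulatory_network(list(A = "B")), "undeclared")
  expect_error(regulatory_network(list(A = "A", A = "!A")), "duplicate")
  expect_error(regulatory_network(list(A = "A"), inputs = "A"),
               "cannot carry a rule")
  expect_error(regulatory_network(list("A")), "must be named")
})

test_that("node order is fixed and locale-independent", {
  net <- regulatory_network(list(b = "a", a = "b", B = "a"))
  expect_identical(net$nodes, c("B", "a", "b"))  # byte-wise order
})

test_that("the packaged model has the published structure", {
  net <- bcell_net()
  expect_length(net$nodes, 22)
  expect_length(net$rules, 17)
  expect_identical(net$inputs, c("Ag", "CD40L", "IL2", "IL21", "IL4"))
  expect_identical(deparse(net$rules$XBP1), "Blimp1 & !Pax5")
  expect_identical(sum(net$categories == "core"), 6L)
  expect_identical(unname(net$categories["Ag"]), "environment")
})

test_that("interaction extraction yields the 39 signed edges including the
           four predicted interactions", {
  ints <- extract_interactions(bcell_net())
  expect_identical(nrow(ints), 39L)
  has <- function(s, t, sg)
    any(ints$source == s & ints$target == t & ints$sign == sg)
  expect_true(has("Pax5", "Bcl6", "positive"))   # predicted
  expect_true(has("Irf4", "Pax5", "negative"))   # predicted
  expect_true(has("Bcl6", "Bcl6", "positive"))   # predicted self-loop
  expect_true(has("Pax5", "Pax5", "positive"))   # predicted self-loop
  expect_true(has("Blimp1", "Bcl6", "negative"))
  expect_true(has("Ag", "BCR", "positive"))
  # no edge is duplicated
  expect_false(anyDuplicated(ints[, c("source", "target")]) > 0)
})

test_that("single-literal self-inhibition extracts one negative edge", {
  net <- regulatory_network(list(A = "!A"))
  ints <- extract_interactions(net)
  expect_identical(ints,
                   data.frame(source = "A", target = "A",
                              sign = "negative"))
})

test_that("a regulator with both signs in one rule is reported, not
           guessed", {
  net <- regulatory_network(list(A = "B & !B", B = "A"))
  expect_error(extract_interactions(net), "ambiguous sign")
})

test_that("each Table-style core pattern is a fixed point of the rule set", {
  net <- bcell_net()
  sig <- cell_type_signatures()
  for (lb in rownames(sig)) {
    s <- make_state(net, colnames(sig)[sig[lb, ] == 1])
    expect_identical(boolean_step(net, s), as_boolean_state(net, s),
                     info = lb)
  }
})

test_that("rule evaluation is pure", {
  net <- bcell_net()
  s <- make_state(net, c("Blimp1", "Pax5"))
  expect_identical(replicate(3, eval_rule(net$rules$XBP1, s)), rep(0L, 3))
})
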