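# Network domain types: validation, rate evaluation, state enumeration.

test_that("network validation resolves every identifier", {
  expect_error(bp_network(list(bp_node("A", rate_up = "B ? 1 : 0"))),
               "undeclared identifier 'B'")
  expect_error(bp_network(list(bp_node("A", rate_up = "$k"))),
               "undeclared parameter '\\$k'")
  expect_error(bp_network(list(bp_node("A"), bp_node("A"))), "duplicate node names")
  expect_error(bp_network(list(bp_node("A")), params = c(k = -1)), "non-negative")
  expect_error(bp_network(list(bp_node("A"), bp_node("D")),
                          death = "D", division = "D"), "must differ")
  expect_error(bp_network(list(bp_node("A")), params = c(k = 1),
                          update_rules = list(z = "p(A)")),
               "undeclared parameter '\\$z'")
})

test_that("evaluate_rate returns the side matching the node's current value", {
  net <- bp_network(list(bp_node("A", rate_up = "$u", rate_down = 5),
                         bp_node("B", rate_up = "A ? $k : 0")),
                    params = c(u = 0.25, k = 0.5))
  expect_equal(evaluate_rate(net, "A", c(A = 0, B = 0)), 0.25)
  # a node ON with constant deactivation rate 5/h (12 min mean) returns 5
  expect_equal(evaluate_rate(net, "A", c(A = 1, B = 0)), 5)
  expect_equal(evaluate_rate(net, "B", c(A = 1, B = 0)), 0.5)
  expect_equal(evaluate_rate(net, "B", c(A = 0, B = 0)), 0)
  expect_error(evaluate_rate(net, "Z", c(A = 0, B = 0)), "unknown node 'Z'")
})

test_that("guarded rates are zero when the guard is false", {
  net <- bp_network(list(bp_node("A"), bp_node("B"),
                         bp_node("C", rate_up = "(A | B) ? $u : 0")),
                    params = c(u = 0.8))
  expect_equal(evaluate_rate(net, "C", c(A = 0, B = 0, C = 0)), 0)
  expect_equal(evaluate_rate(net, "C", c(A = 0, B = 1, C = 0)), 0.8)
})

test_that("state enumeration counts 2^N and the encoding is a bijection", {
  net1 <- one_node_net()
  expect_equal(enumerate_states(net1)$count, 2)
  net3 <- bp_network(list(bp_node("A"), bp_node("B"), bp_node("C")))
  en <- enumerate_states(net3)
  expect_equal(en$count, 8)
  codes <- apply(en$states, 1, function(r)
    encode_state(net3, stats::setNames(r, node_names(net3))))
  expect_equal(sort(codes), 0:7)
  for (code in 0:7)
    expect_equal(encode_state(net3, decode_state(net3, code)), code)
})

test_that("enumeration above the cap refuses the state list but reports the count", {
  nodes <- lapply(1:25, function(i) bp_node(sprintf("N%d", i)))
  net <- bp_network(nodes)
  en <- enumerate_states(net, cap = 20)
  expect_equal(en$count, 2^25)
  expect_null(en$states)
})

test_that("initial-condition masses must sum to one and wildcards split mass evenly", {
  expect_error(bp_initial_condition(list(prob = 0.5, pattern = c(A = 1L))),
               "sum to 1")
  net <- two_indep_net()
  ic <- bp_initial_condition(list(prob = 1, pattern = c(A = 1L, B = NA)))
  p <- bp_expand_initial(net, ic)
  # mass 1 on pattern A=1, B=* -> 0.5 on (A=1,B=0) code 1 and (A=1,B=1) code 3
  expect_equal(p, c(0, 0.5, 0, 0.5))
  ic2 <- bp_initial_condition(list(prob = 0.25, pattern = c(A = 1L)),
                              list(prob = 0.75, pattern = integer(0)))
  expect_equal(bp_expand_initial(net, ic2), c(0.75, 0.25, 0, 0))
})
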