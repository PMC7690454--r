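# Population engine: death/division update phase, parameter updates,
# conservation identities and reduction to the plain CTMC engine.

static_popnet <- function() {
  # frozen network: Death/Division are set only through the initial condition
  bp_network(list(bp_node("Cell"), bp_node("Death"), bp_node("Division")),
             death = "Death", division = "Division")
}

test_that("the update-phase ratio is 1 - P(death) + P(division)", {
  net <- static_popnet()
  states <- matrix(0L, 10, 3, dimnames = list(NULL, node_names(net)))
  states[, "Cell"] <- 1L
  states[1, "Death"] <- 1L          # 10% dying
  states[2:3, "Division"] <- 1L     # 20% dividing
  dist <- bp_distribution(states)
  stp <- population_step(net, dist, dt = 1, seed = 1)
  expect_equal(stp$ratio, 1.1)
  expect_equal(stp$p_death, 0.1)
  expect_equal(stp$p_division, 0.2)
  expect_false(stp$extinct)
  # no state with Division = 1 survives the update phase
  expect_true(all(stp$dist$states[, "Division"] == 0))
  # no dead state survives either
  expect_true(all(stp$dist$states[, "Death"] == 0))
})

test_that("death takes precedence over division when both nodes are set", {
  net <- static_popnet()
  states <- matrix(0L, 4, 3, dimnames = list(NULL, node_names(net)))
  states[, "Cell"] <- 1L
  states[1, c("Death", "Division")] <- 1L  # both set: treated as death
  dist <- bp_distribution(states)
  stp <- population_step(net, dist, dt = 1, seed = 1)
  expect_equal(stp$ratio, 1 - 0.25)
  expect_equal(stp$p_division, 0)
})

test_that("a fully dying population terminates gracefully with an extinction flag", {
  net <- bp_network(list(bp_node("Cell"),
                         bp_node("Death", rate_up = "$d"),
                         bp_node("Division")),
                    params = c(d = 50), death = "Death", division = "Division")
  init <- bp_initial_condition(list(prob = 1, pattern = c(Cell = 1L)))
  expect_warning(tc <- run_population(net, init, dt = 2, n_windows = 10,
                                      n_traj = 200, seed = 1),
                 "extinct")
  expect_true(tc$extinct)
  expect_lt(length(tc$time), 11)
})

test_that("update rules read end-of-window probabilities", {
  net <- bp_network(list(bp_node("ATP"), bp_node("CTL")),
                    params = c(ATP_pop = 0, kill = 0.5, kill_eff = 2),
                    update_rules = list(ATP_pop = "p(ATP)",
                                        kill = "$kill_eff * p(CTL)"))
  states <- matrix(0L, 10, 2, dimnames = list(NULL, c("ATP", "CTL")))
  states[1:4, "ATP"] <- 1L  # p(ATP) = 0.4
  dist <- bp_distribution(states)
  pv <- update_parameters(net, dist)
  expect_equal(pv[["ATP_pop"]], 0.4)
  expect_equal(pv[["kill"]], 0)   # p(CTL) = 0 so the killing rate vanishes
})

test_that("bare node names in update rules mean marginal probabilities", {
  net <- bp_network(list(bp_node("A"), bp_node("B")),
                    params = c(x = 0),
                    update_rules = list(x = "A * p(A & B)"))
  states <- matrix(c(1L, 1L, 0L, 1L, 0L, 0L), 3, 2,
                   dimnames = list(NULL, c("A", "B")))
  dist <- bp_distribution(states)
  pv <- update_parameters(net, dist)
  expect_equal(pv[["x"]], (2 / 3) * (1 / 3))
})

test_that("population size equals the running product of window ratios", {
  cs <- make_birthdeath_case(b = 0.08, delta = 0.03, dt = 2)
  tc <- run_population(cs$network, cs$initial, dt = 2, n_windows = 15,
                       n_traj = 2000, seed = 4)
  expect_equal(tc$size, cumprod(c(1, tc$ratios[-1])), tolerance = 1e-12)
})

test_that("death-only populations shrink monotonically, division-only grow", {
  dcase <- make_birthdeath_case(b = 0, delta = 0.1, dt = 1)
  tc <- run_population(dcase$network, dcase$initial, dt = 1, n_windows = 20,
                       n_traj = 2000, seed = 2)
  expect_true(all(diff(tc$size) <= 0))
  bcase <- make_birthdeath_case(b = 0.1, delta = 0, dt = 1)
  tb <- run_population(bcase$network, bcase$initial, dt = 1, n_windows = 20,
                       n_traj = 2000, seed = 2)
  expect_true(all(diff(tb$size) >= 0))
})

test_that("pure-birth growth matches the window-discretized branching oracle", {
  cs <- make_birthdeath_case(b = 0.05, delta = 0, dt = 1)
  chk <- check_benchmark(cs, n_traj = 20000, n_windows = 20, seed = 1)
  expect_true(chk$pass)
  # and the oracle itself equals the single-node closed form
  expect_equal(cs$oracle(20), (1 + (1 - exp(-0.05)))^20, tolerance = 1e-8)
})

test_that("with no population features the engine reduces to plain estimates", {
  net <- two_indep_net(0.3, 0.8)
  init <- bp_initial_condition(list(prob = 1, pattern = integer(0)))
  n <- 20000
  tc_pop <- run_population(net, init, dt = 2, n_windows = 5, n_traj = n, seed = 6)
  tol <- 3 / sqrt(n)
  for (b in seq_along(tc_pop$time)) {
    t0 <- tc_pop$time[b]
    expect_lt(abs(tc_pop$marginals[b, "A"] - (1 - exp(-0.3 * t0))), tol)
    expect_lt(abs(tc_pop$marginals[b, "B"] - (1 - exp(-0.8 * t0))), tol)
  }
  expect_true(all(tc_pop$size == 1))
})

test_that("population runs are reproducible given the seed", {
  cs <- make_birthdeath_case(b = 0.05, delta = 0.02, dt = 2)
  a <- run_population(cs$network, cs$initial, dt = 2, n_windows = 10,
                      n_traj = 500, seed = 9)
  b <- run_population(cs$network, cs$initial, dt = 2, n_windows = 10,
                      n_traj = 500, seed = 9)
  expect_identical(a$marginals, b$marginals)
  expect_identical(a$size, b$size)
})

test_that("a negative updated parameter is rejected", {
  net <- bp_network(list(bp_node("A")), params = c(x = 0),
                    update_rules = list(x = "p(A) - 1"))
  states <- matrix(0L, 5, 1, dimnames = list(NULL, "A"))
  expect_error(update_parameters(net, bp_distribution(states)), "invalid value")
})
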