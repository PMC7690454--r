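# Trajectory engine against closed forms and the master-equation oracle.

test_that("an all-zero-rate network is absorbing", {
  net <- bp_network(list(bp_node("A"), bp_node("B")))
  tr <- simulate_trajectory(net, c(A = 1, B = 0), t_max = 50, seed = 1)
  expect_equal(nrow(tr$jumps), 0)
  expect_equal(tr$end_state, c(A = 1, B = 0))
})

test_that("trajectory jumps are ordered and flip one node at a time", {
  cs <- make_random_network(5, density = 0.5, seed = 3)
  tr <- simulate_trajectory(cs$network, net_state(cs$network), t_max = 20, seed = 7)
  expect_true(all(diff(tr$jumps$time) > 0))
  expect_true(all(tr$jumps$time <= 20))
  # replaying the flips from the start state reproduces the end state
  st <- net_state(cs$network)
  for (nd in tr$jumps$node) st[nd] <- 1 - st[nd]
  expect_equal(st, tr$end_state)
})

test_that("single-node activation matches the closed form 1 - exp(-kt)", {
  net <- one_node_net(0.25)
  ex <- exact_transient(net, c(A = 0), t = 4)
  expect_equal(ex[2], 1 - exp(-1), tolerance = 1e-9)
  tc <- estimate_probabilities(net, c(A = 0), t_max = 8, dt = 1,
                               n_traj = 50000, seed = 1)
  expect_lt(abs(tc$marginals[5, "A"] - (1 - exp(-1))), 3 / sqrt(50000))
  # empirical mean first flip over 10,000 trajectories is close to 1/k = 4 h
  tf <- estimate_probabilities(net, c(A = 0), t_max = 400, dt = 400,
                               n_traj = 10000, seed = 2, track_first = TRUE)
  expect_equal(mean(tf$first_on[, "A"]), 4, tolerance = 0.05)
})

test_that("independent nodes factorize: joint = product of marginals", {
  net <- two_indep_net(0.25, 0.5)
  tc <- estimate_probabilities(net, c(A = 0, B = 0), t_max = 6, dt = 2,
                               n_traj = 50000, seed = 5, track_states = TRUE)
  tol <- 3 / sqrt(50000)
  for (g in seq_along(tc$time)) {
    t0 <- tc$time[g]
    pa <- 1 - exp(-0.25 * t0)
    pb <- 1 - exp(-0.5 * t0)
    joint <- c((1 - pa) * (1 - pb), pa * (1 - pb), (1 - pa) * pb, pa * pb)
    expect_lt(max(abs(tc$state_probs[g, ] - joint)), tol)
  }
})

test_that("exact_transient returns the initial distribution at t = 0 and conserves mass", {
  cs <- make_random_network(4, density = 0.4, seed = 11)
  p0 <- bp_expand_initial(cs$network, cs$initial)
  expect_equal(exact_transient(cs$network, cs$initial, 0), p0)
  pt <- exact_transient(cs$network, cs$initial, 7)
  expect_equal(sum(pt), 1, tolerance = 1e-9)
  expect_true(all(pt >= -1e-12))
})

test_that("exact_transient refuses networks above the size cap", {
  nodes <- lapply(1:13, function(i) bp_node(sprintf("N%d", i), rate_up = 1))
  net <- bp_network(nodes)
  expect_error(exact_transient(net, net_state(net), 1), "refuses")
})

test_that("stochastic estimates agree with the exact oracle on random networks", {
  tol <- 3 / sqrt(50000)
  for (s in c(2, 9)) {
    cs <- make_random_network(4, density = 0.5, seed = s)
    tc <- estimate_probabilities(cs$network, cs$initial, t_max = 6, dt = 2,
                                 n_traj = 50000, seed = s, track_states = TRUE)
    for (g in 2:length(tc$time)) {
      exact <- exact_transient(cs$network, cs$initial, tc$time[g])
      expect_lt(max(abs(tc$state_probs[g, ] - exact)), tol)
    }
  }
})

test_that("waiting times are exponential (KS test at the 1% level, n = 10,000)", {
  net <- one_node_net(0.25)
  tf <- estimate_probabilities(net, c(A = 0), t_max = 1000, dt = 1000,
                               n_traj = 10000, seed = 3, track_first = TRUE)
  times <- tf$first_on[, "A"]
  expect_false(anyNA(times))
  ks <- suppressWarnings(stats::ks.test(times, stats::pexp, rate = 0.25))
  expect_gt(ks$p.value, 0.01)
})

test_that("identical seeds give identical results; different seeds differ", {
  net <- two_indep_net()
  a <- estimate_probabilities(net, c(A = 0, B = 0), t_max = 10, dt = 1,
                              n_traj = 500, seed = 42)
  b <- estimate_probabilities(net, c(A = 0, B = 0), t_max = 10, dt = 1,
                              n_traj = 500, seed = 42)
  d <- estimate_probabilities(net, c(A = 0, B = 0), t_max = 10, dt = 1,
                              n_traj = 500, seed = 43)
  expect_identical(a$marginals, b$marginals)
  expect_false(identical(a$marginals, d$marginals))
  t1 <- simulate_trajectory(net, c(A = 0, B = 0), 10, seed = 8)
  t2 <- simulate_trajectory(net, c(A = 0, B = 0), 10, seed = 8)
  expect_identical(t1$jumps, t2$jumps)
})

test_that("invalid rates are reported with the node name", {
  net <- bp_network(list(bp_node("A", rate_up = "$k - 1")), params = c(k = 0.5))
  expect_error(simulate_trajectory(net, c(A = 0), 5, seed = 1), "node 'A'")
  expect_error(evaluate_rate(net, "A", c(A = 0)), "node 'A'")
})
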