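# Shipped ICD models: structural counts, adopted parameter values,
# scenarios, cell-type summaries.

test_that("the phenomenological model has the documented structure", {
  m <- build_phenomenological()
  expect_equal(n_nodes(m$network), 13)
  expect_equal(enumerate_states(m$network, cap = 13)$count, 8192)
  expect_length(m$network$params, 19)
  expect_length(m$network$update_rules, 5)
  expect_length(manual_parameters(m$network), 14)
  # population-updated parameters start at 0
  expect_true(all(m$network$params[names(m$network$update_rules)] == 0))
  # adopted timings: danger signals at 4 h (CALR, ATP) and 6 h (HMGB1)
  expect_equal(1 / m$network$params[["u_CALR"]], 4)
  expect_equal(1 / m$network$params[["u_ATP"]], 4)
  expect_equal(1 / m$network$params[["u_HMGB1"]], 6)
  # total DC transit to the lymph node: 5 days
  expect_equal(1 / m$network$params[["u_MigrDC"]] +
               1 / m$network$params[["u_LNodeDC"]], 120)
  # T-cell differentiation 2 days; divisions 10 days (tumour) / 12 h (CTL)
  expect_equal(1 / m$network$params[["u_CTL"]], 48)
  expect_equal(1 / m$network$params[["div_tumor"]], 240)
  expect_equal(1 / m$network$params[["clonal_exp_rate"]], 12)
  expect_equal(m$network$params[["direct_cyt"]], 1 / 50000)
})

test_that("the extended model has the documented structure", {
  m <- build_extended()
  expect_equal(n_nodes(m$network), 57)
  expect_length(m$network$params, 98)
  expect_length(m$network$update_rules, 20)
  expect_length(manual_parameters(m$network), 78)
  expect_true(all(m$network$params[names(m$network$update_rules)] == 0))
  p <- m$network$params
  expect_equal(p[["InitDC"]], 0.1)
  expect_equal(p[["clonal_exp_rate"]], 0.05)
  expect_equal(p[["d_ChemoT"]], log(2) / 72)   # 3-day half-life
  expect_equal(1 / p[["u_CTL"]], 2.4)
  expect_equal(1 / p[["u_TumorDiv"]], 100000)
  expect_equal(p[["direct_cyt"]], 1 / 50000)
  # DAMP exposure: ATP and CALR at 4 h, others at 6 h
  expect_equal(1 / p[["u_ATP"]], 4)
  expect_equal(1 / p[["u_CALR"]], 4)
  expect_equal(1 / p[["u_HMGB1"]], 6)
  # fast cell-state activation: 12 min
  expect_equal(1 / p[["u_aDC"]], 0.2)
  expect_equal(1 / p[["u_preCTL"]], 0.2)
  # protein degradation: 12 min
  expect_equal(1 / p[["d_IL2"]], 0.2)
  # initial mix 80/10/5/5
  probs <- vapply(m$initial$atoms, function(a) a$prob, numeric(1))
  expect_equal(probs, c(0.8, 0.1, 0.05, 0.05))
})

test_that("the TCR-I rule requires CD28 and a naive CD8 cell", {
  m <- build_extended()
  st <- net_state(m$network, on = c("cd8", "CD28"))
  # with CD28 and cd8 present the rate is the (population-updated) TCR-I rate
  expect_equal(evaluate_rate(m$network, "TCR_I", st, params = c(k_TCR_I = 0.7)), 0.7)
  st2 <- net_state(m$network, on = "cd8")
  expect_equal(evaluate_rate(m$network, "TCR_I", st2, params = c(k_TCR_I = 0.7)), 0)
})

test_that("scenarios apply, invert, and reject bad targets", {
  m <- build_extended()
  ko <- apply_scenario(m, "cd28_ko")
  expect_identical(ko$network$nodes[["CD28"]]$rate_up, list(kind = "num", value = 0))
  back <- revert_scenario(ko)
  expect_identical(model_fingerprint(back$network, back$initial),
                   model_fingerprint(m$network, m$initial))
  # empty scenario leaves the model unchanged
  none <- apply_scenario(m, bp_scenario("none", list()))
  expect_identical(model_fingerprint(none$network, none$initial),
                   model_fingerprint(m$network, m$initial))
  expect_error(apply_scenario(m, "unknown_scenario"), "available")
  expect_error(apply_scenario(m, bp_scenario("bad",
    list(list(type = "clamp_off", node = "NoSuchNode")))), "NoSuchNode")
  expect_error(apply_scenario(m, bp_scenario("bad",
    list(list(type = "set_param", param = "nope", value = 1)))), "nope")
})

test_that("no_clonal_expansion zeroes the lymphocyte division rate", {
  ph <- apply_scenario(build_phenomenological(), "no_clonal_expansion")
  expect_equal(ph$network$params[["clonal_exp_rate"]], 0)
})

test_that("CD28 knock-out structurally blocks the CTL compartment", {
  # CTL requires TCR_I, which requires CD28; with CD28 clamped OFF the CTL
  # marginal is exactly zero in any run
  ko <- apply_scenario(build_extended(), "cd28_ko")
  tc <- run_icd(ko, n_windows = 30, n_traj = 300, seed = 1)
  expect_equal(max(tc$marginals[, "CTL"]), 0)
  expect_equal(max(tc$marginals[, "cd4_Act"]), 0)
})

test_that("cell-type curves follow probability times population size", {
  # frozen phenomenological model: no transitions, mass stays on the inputs
  ph <- build_phenomenological()
  frozen <- stats::setNames(rep(0, length(manual_parameters(ph$network))),
                            manual_parameters(ph$network))
  m <- build_phenomenological(params = frozen)
  tc <- run_icd(m, n_windows = 5, n_traj = 500, seed = 1)
  s <- summarize_celltypes(tc)
  tum <- s$curves[s$curves$celltype == "Tumor", ]
  expect_equal(tum$absolute, rep(tum$absolute[1], 6), tolerance = 1e-12)
  expect_true(all(tc$size == 1))
  expect_equal(s$readouts$final[s$readouts$celltype == "CTL"], 0)
  # clearance never happens for a constant curve
  expect_true(is.na(s$readouts$clearance_time[s$readouts$celltype == "Tumor"]))
})

test_that("curve readouts behave on simple shapes", {
  tm <- seq(0, 10, by = 1)
  expect_equal(clearance_time(tm, c(10, 8, 5, 2, 0.05, 0, 0, 0, 0, 0, 0)), 4)
  expect_true(is.na(clearance_time(tm, rep(2, 11))))
  expect_equal(peak_time(tm, c(0, 1, 3, 7, 4, 2, 1, 0, 0, 0, 0)), 3)
  # half-max 5 is crossed between t = 3 (value 2) and t = 4 (value 6)
  expect_equal(activation_time(tm, c(0, 0, 1, 2, 6, 9, 10, 10, 10, 10, 10)), 3.75)
  expect_true(is.na(activation_time(tm, rep(0, 11))))
})
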