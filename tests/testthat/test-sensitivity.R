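# Sensitivity scans: variant construction, fold conventions, ranking.

test_that("variant counts follow the manually-set parameter count", {
  expect_equal(nrow(make_variants(build_extended(), 1.5)), 156)   # 78 x 2
  expect_equal(nrow(make_variants(build_phenomenological(), 1.5)), 28)  # 14 x 2
  expect_error(make_variants(build_extended(), 1), "factor")
  expect_error(make_variants(build_extended(), 0.5), "factor")
})

test_that("Less divides and More multiplies (division convention)", {
  v <- make_variants(build_extended(), 1.5)
  expect_equal(round(v$value[v$variant == "Less_InitDC"], 3), 0.067)
  expect_equal(v$value[v$variant == "More_InitDC"], 0.15)
  expect_equal(round(v$value[v$variant == "Less_clonal_exp_rate"], 3), 0.033)
  expect_equal(v$value[v$variant == "More_clonal_exp_rate"], 0.075)
})

test_that("More and Less are exact multiplicative inverses", {
  for (f in c(1.5, 5)) {
    v <- make_variants(build_phenomenological(), f)
    base <- build_phenomenological()$network$params
    for (p in unique(v$param)) {
      more <- v$value[v$param == p & v$direction == "More"]
      less <- v$value[v$param == p & v$direction == "Less"]
      expect_equal(less * f, base[[p]])   # More applied to Less restores base
      expect_equal(more / f, base[[p]])   # Less applied to More restores base
    }
  }
})

# a small, fast population model for scan machinery tests: tumour decays at a
# constant treatment-controlled rate, so variant effects are analytic
toy_scan_model <- function() {
  net <- bp_network(list(
    bp_node("Cell"),
    bp_node("Death", rate_up = "Cell ? $d : 0"),
    bp_node("Division")),
    params = c(d = 0.05), death = "Death", division = "Division")
  init <- bp_initial_condition(list(prob = 1, pattern = c(Cell = 1L)))
  bp_model(net, init, celltypes = list(Tumor = "Cell"),
           settings = c(time_step = 2, horizon = 40))
}

test_that("the WT scan row equals an independent run with the recorded seed", {
  mod <- toy_scan_model()
  v <- make_variants(mod, 1.5)
  res <- run_scan(mod, v, readout_times = c(20, 40), n_traj = 500, seed = 11)
  expect_equal(nrow(res), 3)  # 2 variants + WT
  wt <- res[res$variant == "WT", ]
  tc <- run_icd(mod, dt = 2, n_windows = 20, n_traj = 500, seed = wt$seed)
  abs_curve <- tc$celltype_probs[, "Tumor"] * tc$size
  expect_equal(wt$tumor_20h, abs_curve[tc$time == 20])
  expect_equal(wt$tumor_40h, abs_curve[tc$time == 40])
})

test_that("scans are reproducible and More/Less order as expected", {
  mod <- toy_scan_model()
  v <- make_variants(mod, 1.5)
  r1 <- run_scan(mod, v, readout_times = c(40), n_traj = 1000, seed = 5)
  r2 <- run_scan(mod, v, readout_times = c(40), n_traj = 1000, seed = 5)
  expect_identical(r1, r2)
  # faster death (More_d) leaves less tumour than WT; slower death more
  expect_lt(r1$tumor_40h[r1$variant == "More_d"], r1$tumor_40h[r1$variant == "WT"])
  expect_gt(r1$tumor_40h[r1$variant == "Less_d"], r1$tumor_40h[r1$variant == "WT"])
})

test_that("rank_effects orders by absolute effect with lexicographic ties", {
  res <- data.frame(variant = c("WT", "More_a", "Less_a", "More_b", "Less_b"),
                    param = c(NA, "a", "a", "b", "b"),
                    direction = c("WT", "More", "Less", "More", "Less"),
                    value = c(NA, 2, 0.5, 2, 0.5),
                    seed = 1:5, extinct = FALSE,
                    tumor_100h = c(0.5, 0.5, 0.5, 0.1, 0.9),
                    stringsAsFactors = FALSE)
  class(res) <- c("bp_scan_result", "data.frame")
  rk <- rank_effects(res)
  # the two b variants have |delta| = 0.4 and rank above the zero-effect a's
  expect_setequal(rk$variant[rk$rank <= 2], c("More_b", "Less_b"))
  # zero-effect variants are tie-broken lexicographically
  expect_identical(rk$variant[rk$rank >= 3], sort(c("More_a", "Less_a")))
  # permutation invariance
  perm <- res[c(4, 2, 1, 5, 3), ]
  class(perm) <- c("bp_scan_result", "data.frame")
  expect_identical(rank_effects(perm), rk)
})
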