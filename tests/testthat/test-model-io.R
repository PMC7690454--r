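# bnd/cfg/upp dialect reader and writer.

test_that("a parsed model resolves rules, parameters and initial condition", {
  bnd <- "
node A {
  rate_up = $u;
  rate_down = 0;
}
node B {
  rate_up = A ? $k : 0; // guarded activation
}
"
  cfg <- "
$u = 0.25;
$k = 0.5;
init 1 : -;
set time_step = 2;
"
  m <- parse_model(bnd, cfg)
  expect_equal(n_nodes(m$network), 2)
  expect_equal(m$network$params[["k"]], 0.5)
  expect_equal(m$settings[["time_step"]], 2)
  expect_null(m$network$death_node)
  expect_length(m$network$update_rules, 0)
  # direct substitution: rate of B with A on is $k
  expect_equal(evaluate_rate(m$network, "B", c(A = 1, B = 0)), 0.5)
})

test_that("the upp file adds population features", {
  bnd <- "node Cell {\n rate_up = 0;\n}\nnode Death {\n}\nnode Division {\n rate_up = Cell ? $b : 0;\n}"
  cfg <- "$b = 0.05;\n$b_pop = 0;\ninit 1 : Cell = 1;"
  upp <- "death Death;\ndivision Division;\nupdate $b_pop = p(Cell);"
  m <- parse_model(bnd, cfg, upp)
  expect_identical(m$network$death_node, "Death")
  expect_identical(m$network$division_node, "Division")
  expect_named(m$network$update_rules, "b_pop")
})

test_that("parse errors name the symbol and the line", {
  bnd_bad <- "node A {\n  rate_up = B ? 1 : 0;\n}"
  expect_error(parse_model(bnd_bad, ""), "undeclared identifier 'B'")
  expect_error(parse_model("node A {\n  rate = 1;\n}", ""), "line 2")
  expect_error(parse_model("node A {\n rate_up = 0;\n}", "$k = -2;"), "negative")
  expect_error(parse_model("node A {\n rate_up = 0;\n}",
                           "init 0.6 : A = 1;"), "sum to 1")
  expect_error(parse_model("node A {\n rate_up = 0;\n}",
                           "init 1 : Z = 1;"), "undeclared node 'Z'")
})

test_that("write/parse round-trips are semantically identical", {
  # generated random networks and both shipped models
  models <- c(lapply(1:3, function(s) {
    cs <- make_random_network(4, density = 0.5, seed = s)
    list(network = cs$network, initial = cs$initial)
  }),
  list(build_phenomenological()[c("network", "initial")],
       build_extended()[c("network", "initial")]))
  for (m in models) {
    txt <- write_model(m$network, m$initial, c(time_step = 2))
    back <- parse_model(txt$bnd, txt$cfg, txt$upp)
    expect_identical(model_fingerprint(back$network, back$initial, back$settings),
                     txt)
    # parameter maps and node sets agree exactly
    expect_setequal(node_names(back$network), node_names(m$network))
    expect_equal(back$network$params[sort(names(back$network$params))],
                 m$network$params[sort(names(m$network$params))])
    # rate expressions evaluate identically on every state (small N only)
    if (n_nodes(m$network) <= 6) {
      sts <- enumerate_states(m$network)$states
      for (nd in node_names(m$network)) {
        for (r in seq_len(nrow(sts))) {
          st <- stats::setNames(as.numeric(sts[r, ]), colnames(sts))
          expect_equal(evaluate_rate(back$network, nd, st),
                       evaluate_rate(m$network, nd, st))
        }
      }
    }
  }
})

test_that("a model with no parameters writes a cfg of just init and settings", {
  net <- bp_network(list(bp_node("A", rate_up = 1)))
  txt <- write_model(net, bp_initial_condition(list(prob = 1, pattern = integer(0))),
                     c(horizon = 10))
  expect_false(grepl("\\$", txt$cfg))
  expect_match(txt$cfg, "init 1 : -;", fixed = TRUE)
  expect_match(txt$cfg, "set horizon = 10;", fixed = TRUE)
})

test_that("shipped model files parse back to the builders' models", {
  for (nm in c("phenomenological", "extended")) {
    files <- icd_model_files(nm)
    parsed <- read_model(files[["bnd"]], files[["cfg"]], files[["upp"]])
    built <- if (nm == "phenomenological") build_phenomenological() else build_extended()
    expect_identical(
      model_fingerprint(parsed$network, parsed$initial, parsed$settings),
      model_fingerprint(built$network, built$initial, built$settings))
  }
})

test_that("JSON export carries nodes, parameters and update rules", {
  m <- build_phenomenological()
  doc <- jsonlite::fromJSON(model_to_json(m$network, m$initial, m$settings))
  expect_length(doc$nodes, 13)
  expect_length(doc$parameters, 19)
  expect_length(doc$update_rules, 5)
  expect_identical(doc$death_node, "Death")
})
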