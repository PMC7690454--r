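# Synthetic benchmark networks with known reference solutions. Every engine
# feature is testable against one of these cases without external data:
# independent activation chains have product-form closed solutions,
# birth-death population toys follow a window-discretized branching
# recursion, and random guarded networks are checked against the
# master-equation oracle. The Monte-Carlo tolerance is 3/sqrt(n_traj) per
# probability (about three standard errors of a Bernoulli proportion).

#' Benchmark case: independent activation chain
#'
#' `n` nodes that activate independently with constant rates and never
#' deactivate. The transient solution is `P(node_i ON at t) = 1 - exp(-k_i t)`
#' with product-form joint probabilities.
#'
#' @param n Number of nodes (>= 1).
#' @param rates Activation rates (1/h), recycled to length `n`.
#' @return An object of class `bp_benchmark` with fields `network`,
#'   `initial`, `oracle(t)` (exact state distribution, code order), and
#'   `tolerance(n_traj)`.
#' @export
make_independent_chain <- function(n, rates = 0.25) {
  stopifnot(n >= 1, all(rates > 0))
  rates <- rep_len(rates, n)
  nodes <- lapply(seq_len(n), function(i)
    bp_node(sprintf("N%d", i), rate_up = sprintf("$k%d", i)))
  params <- stats::setNames(rates, sprintf("k%d", seq_len(n)))
  net <- bp_network(nodes, params = params)
  init <- bp_initial_condition(list(prob = 1, pattern = integer(0)))
  oracle <- function(t) {
    p_on <- 1 - exp(-rates * t)
    codes <- 0:(2^n - 1)
    vapply(codes, function(code) {
      bits <- bitwAnd(code %/% 2^(seq_len(n) - 1), 1L)
      prod(ifelse(bits == 1, p_on, 1 - p_on))
    }, numeric(1))
  }
  structure(list(name = sprintf("independent_chain_n%d", n),
                 network = net, initial = init, oracle = oracle,
                 kind = "transient",
                 tolerance = function(n_traj) 3 / sqrt(n_traj)),
            class = "bp_benchmark")
}

#' Benchmark case: birth-death population toy
#'
#' A single always-ON cell node plus Division (rate `b`) and Death (rate
#' `delta`). The reference population size after `k` windows of length `dt`
#' follows the window-discretized branching recursion, with the per-window
#' death/division probabilities computed by the master-equation oracle
#' (independent of the trajectory kernel).
#'
#' @param b Division rate (1/h, >= 0).
#' @param delta Death rate (1/h, >= 0).
#' @param dt Window length in hours.
#' @return A `bp_benchmark` whose `oracle(k)` returns the expected
#'   population-size factor after `k` windows.
#' @export
make_birthdeath_case <- function(b, delta, dt) {
  stopifnot(b >= 0, delta >= 0, dt > 0)
  net <- bp_network(list(bp_node("Cell"),
                         bp_node("Division", rate_up = "Cell ? $b : 0"),
                         bp_node("Death", rate_up = "Cell ? $delta : 0")),
                    params = c(b = b, delta = delta),
                    death = "Death", division = "Division")
  init <- bp_initial_condition(list(prob = 1, pattern = c(Cell = 1)))
  oracle <- function(k) {
    # every window starts from (Cell=1, Division=0, Death=0): one exact
    # window propagation gives the constant per-window ratio
    p <- exact_transient(net, c(Cell = 1, Division = 0, Death = 0), dt)
    states <- enumerate_states(net)$states
    d <- sum(p[states[, "Death"] == 1])
    bp <- sum(p[states[, "Division"] == 1 & states[, "Death"] == 0])
    (1 - d + bp)^k
  }
  structure(list(name = sprintf("birthdeath_b%g_d%g", b, delta),
                 network = net, initial = init, oracle = oracle,
                 kind = "population", dt = dt,
                 tolerance = function(n_traj) 3 / sqrt(n_traj)),
            class = "bp_benchmark")
}

#' Benchmark case: random guarded network
#'
#' Each node receives a random set of regulators (edge probability
#' `density`); its activation rate is a guarded expression
#' `(<OR of regulators>) ? k_hi : k_lo` with rates drawn uniformly from
#' `rate_range`, and its deactivation rate is constant. With `n <= 8` the
#' case carries the master-equation oracle; larger cases are flagged
#' property-only (`oracle = NULL`).
#'
#' @param n Number of nodes.
#' @param density Edge probability in `[0, 1]`; 0 reduces to an independent
#'   chain.
#' @param rate_range Length-2 numeric range for sampled rates (1/h).
#' @param seed Integer seed; the same seed reproduces the same network.
#' @return A `bp_benchmark`.
#' @export
make_random_network <- function(n, density = 0.3, rate_range = c(0.1, 2),
                                seed = 1) {
  stopifnot(n >= 1, density >= 0, density <= 1)
  u <- bp_rng_runif(n * n + 3 * n, seed)
  adj <- matrix(u[seq_len(n * n)] < density, n, n)
  diag(adj) <- FALSE
  rr <- function(x) rate_range[1] + x * (rate_range[2] - rate_range[1])
  k_hi <- rr(u[n * n + seq_len(n)])
  k_lo <- 0.1 * rr(u[n * n + n + seq_len(n)])
  k_dn <- 0.5 * rr(u[n * n + 2 * n + seq_len(n)])
  nodes <- lapply(seq_len(n), function(i) {
    regs <- which(adj[, i])
    up <- if (length(regs))
      sprintf("(%s) ? $hi%d : $lo%d", paste(sprintf("N%d", regs), collapse = " | "), i, i)
    else sprintf("$hi%d", i)
    bp_node(sprintf("N%d", i), rate_up = up, rate_down = sprintf("$dn%d", i))
  })
  params <- stats::setNames(c(k_hi, k_lo, k_dn),
                            c(sprintf("hi%d", 1:n), sprintf("lo%d", 1:n),
                              sprintf("dn%d", 1:n)))
  net <- bp_network(nodes, params = params)
  init <- bp_initial_condition(list(prob = 1, pattern = integer(0)))
  oracle <- if (n <= 8) function(t) exact_transient(net, init, t) else NULL
  structure(list(name = sprintf("random_n%d_seed%d", n, seed),
                 network = net, initial = init, oracle = oracle,
                 kind = if (is.null(oracle)) "property_only" else "transient",
                 tolerance = function(n_traj) 3 / sqrt(n_traj)),
            class = "bp_benchmark")
}

#' @export
print.bp_benchmark <- function(x, ...) {
  cat(sprintf("Benchmark case '%s' (%s): %d nodes%s\n", x$name, x$kind,
              n_nodes(x$network),
              if (is.null(x$oracle)) ", no oracle (property-only)" else ""))
  invisible(x)
}

#' Check a benchmark case against its reference solution
#'
#' Runs the stochastic engine on the case and compares with the oracle:
#' transient cases compare every state mass at every grid time, population
#' cases compare the relative error of the final size factor.
#'
#' @param case A `bp_benchmark`.
#' @param n_traj Trajectories (tolerance scales as `3/sqrt(n_traj)`).
#' @param t_max Horizon in hours (transient cases).
#' @param dt Grid/window step.
#' @param n_windows Windows (population cases).
#' @param seed Integer seed.
#' @return A list with `pass`, `max_err`, `tol`, `name`.
#' @export
check_benchmark <- function(case, n_traj = 5000, t_max = 10, dt = 2,
                            n_windows = 20, seed = 1) {
  tol <- case$tolerance(n_traj)
  if (case$kind == "population") {
    tc <- run_population(case$network, case$initial, dt = case$dt,
                         n_windows = n_windows, n_traj = n_traj, seed = seed)
    expect <- case$oracle(n_windows)
    err <- abs(tc$size[length(tc$size)] - expect) / expect
  } else if (case$kind == "transient") {
    tc <- estimate_probabilities(case$network, case$initial, t_max = t_max,
                                 dt = dt, n_traj = n_traj, seed = seed,
                                 track_states = TRUE)
    err <- 0
    for (g in seq_along(tc$time)) {
      expect <- case$oracle(tc$time[g])
      err <- max(err, max(abs(tc$state_probs[g, ] - expect)))
    }
  } else {
    stop(sprintf("case '%s' has no oracle", case$name), call. = FALSE)
  }
  list(name = case$name, pass = err <= tol, max_err = err, tol = tol)
}

#' Run the standard benchmark suite
#'
#' @param n_traj Trajectories per case.
#' @param seed Integer seed.
#' @return Data frame with one row per case (`name`, `max_err`, `tol`,
#'   `pass`).
#' @export
run_benchmark_suite <- function(n_traj = 5000, seed = 1) {
  cases <- list(
    make_independent_chain(1, 0.25),
    make_independent_chain(3, c(0.25, 0.5, 1)),
    make_birthdeath_case(b = 0.05, delta = 0, dt = 1),
    make_birthdeath_case(b = 0.02, delta = 0.05, dt = 2),
    make_random_network(4, density = 0.4, seed = seed),
    make_random_network(6, density = 0.3, seed = seed + 1)
  )
  rows <- lapply(cases, function(cs)
    as.data.frame(check_benchmark(cs, n_traj = n_traj, seed = seed)))
  do.call(rbind, rows)[, c("name", "max_err", "tol", "pass")]
}
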