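#' Simulate a single stochastic trajectory
#'
#' Gillespie semantics: from state `x`, node `i` flips with rate
#' `rate_up_i(x)` if `x_i = 0` and `rate_down_i(x)` if `x_i = 1`; the waiting
#' time to the next jump is exponential with the summed rate, and the flipped
#' node is drawn proportionally to its rate. A state with total rate 0 is
#' absorbing until `t_max`.
#'
#' @param net A [bp_network()].
#' @param start Named 0/1 vector, the initial state.
#' @param t_max Simulation horizon (hours, > 0).
#' @param seed Integer seed for the trajectory's RNG stream.
#' @param params Optional parameter overrides.
#' @return An object of class `bp_trajectory`: a list with `start`,
#'   `jumps` (data frame `time`, `node`), `end_state`, `t_max`.
#' @export
simulate_trajectory <- function(net, start, t_max, seed = 1, params = NULL) {
  stopifnot(t_max > 0)
  start <- bp_check_state(net, start)
  comp <- bp_compile_network(net)
  pv <- bp_param_vector(net, params)
  res <- bp_cpp_trajectory(comp, pv, as.integer(start), t_max, as.numeric(seed))
  jumps <- data.frame(time = res$time,
                      node = names(net$nodes)[res$node],
                      stringsAsFactors = FALSE)
  structure(list(start = start, jumps = jumps,
                 end_state = stats::setNames(res$end_state, names(net$nodes)),
                 t_max = t_max),
            class = "bp_trajectory")
}

#' @export
print.bp_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d jumps over [0, %g] h\n", nrow(x$jumps), x$t_max))
  invisible(x)
}

#' Estimate node and state probabilities by Monte Carlo
#'
#' Averages `n_traj` independent trajectories sampled from the initial
#' condition. Curves are sampled at grid points (the state at the grid time),
#' and the output is deterministic given `seed`.
#'
#' @param net A [bp_network()].
#' @param initial A [bp_initial_condition()], or a single named 0/1 state.
#' @param t_max Horizon in hours.
#' @param dt Grid step in hours (> 0).
#' @param n_traj Number of trajectories (>= 1).
#' @param seed Integer seed.
#' @param track_states If `TRUE` (requires <= 16 nodes) per-state
#'   probability curves are recorded alongside node marginals.
#' @param track_first If `TRUE`, per-trajectory first-activation times are
#'   recorded for every node (`NA` when the node never turns on).
#' @param params Optional parameter overrides.
#' @return An object of class `bp_timecourse`: `time` (grid), `marginals`
#'   (matrix time x node), optionally `state_probs` (time x 2^N, columns in
#'   state-code order) and `first_on` (n_traj x node), plus `n_traj`, `seed`.
#' @export
estimate_probabilities <- function(net, initial, t_max, dt = 1, n_traj = 1000,
                                   seed = 1, track_states = FALSE,
                                   track_first = FALSE, params = NULL) {
  stopifnot(n_traj >= 1, dt > 0, t_max > 0)
  if (!inherits(initial, "bp_initial_condition")) {
    st <- bp_check_state(net, initial)
    initial <- bp_initial_condition(list(prob = 1, pattern = st))
  }
  grid <- seq(0, t_max, by = dt)
  comp <- bp_compile_network(net)
  pv <- bp_param_vector(net, params)
  start <- bp_sample_initial(net, initial, n_traj, seed = bp_derive_seed(seed, 1))
  res <- bp_cpp_simulate(comp, pv, start, t_max, grid, as.numeric(seed),
                         track_states, track_first)
  colnames(res$marginals) <- names(net$nodes)
  out <- list(time = grid, marginals = res$marginals, n_traj = n_traj,
              seed = seed, end_states = res$end_states)
  if (track_states) out$state_probs <- res$state_probs
  if (track_first) {
    colnames(res$first_on) <- names(net$nodes)
    out$first_on <- res$first_on
  }
  structure(out, class = "bp_timecourse")
}

#' @export
print.bp_timecourse <- function(x, ...) {
  cat(sprintf("Timecourse: %d nodes on [0, %g] h (%d grid points, %d trajectories)\n",
              ncol(x$marginals), max(x$time), length(x$time), x$n_traj))
  invisible(x)
}

#' Tidy data frame of a timecourse
#' @param x A `bp_timecourse`.
#' @param ... Unused.
#' @return Data frame with columns `time`, `node`, `probability`.
#' @export
as.data.frame.bp_timecourse <- function(x, ...) {
  data.frame(time = rep(x$time, times = ncol(x$marginals)),
             node = rep(colnames(x$marginals), each = length(x$time)),
             probability = as.vector(x$marginals),
             stringsAsFactors = FALSE)
}

# stable derived seeds (kept below 2^31)
bp_derive_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 104729 * as.numeric(k)) %% 2147483629
}

#' Exact transient distribution by the master equation
#'
#' Builds the full `2^N x 2^N` generator of the Markov jump process and
#' propagates the initial distribution with a matrix exponential:
#' `P(t) = expm(Q t) P(0)`. Intended as a validation oracle for the
#' trajectory engine; refuses networks with more than `cap` nodes.
#'
#' This path evaluates rate expressions in R and shares no code with the
#' C++ simulation kernel.
#'
#' @param net A [bp_network()].
#' @param initial A [bp_initial_condition()] or named 0/1 state.
#' @param t Time (hours, >= 0).
#' @param cap Maximum node count (default 12).
#' @param params Optional parameter overrides.
#' @return Numeric vector of length `2^N`: state probabilities indexed by
#'   state code + 1; sums to 1 within 1e-9.
#' @export
exact_transient <- function(net, initial, t, cap = 12, params = NULL) {
  N <- n_nodes(net)
  if (N > cap)
    stop(sprintf("exact_transient refuses networks with more than %d nodes", cap),
         call. = FALSE)
  stopifnot(t >= 0)
  if (!inherits(initial, "bp_initial_condition")) {
    st <- bp_check_state(net, initial)
    initial <- bp_initial_condition(list(prob = 1, pattern = st))
  }
  p0 <- bp_expand_initial(net, initial)
  if (t == 0) return(p0)
  Q <- bp_generator_matrix(net, params)
  pt <- as.numeric(Matrix::expm(Q * t) %*% p0)
  if (abs(sum(pt) - 1) > 1e-9)
    stop("master-equation propagation lost probability mass", call. = FALSE)
  pt
}

# Generator in column convention: dP/dt = Q P with Q[to, from] the flip rate.
bp_generator_matrix <- function(net, params = NULL) {
  N <- n_nodes(net)
  nn <- names(net$nodes)
  pv <- bp_param_vector(net, params)
  states <- enumerate_states(net, cap = 20)$states
  n_states <- nrow(states)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  for (s in seq_len(n_states)) {
    st <- stats::setNames(as.numeric(states[s, ]), nn)
    total <- 0
    for (i in seq_len(N)) {
      r <- evaluate_rate(net, nn[i], st, pv)
      if (r > 0) {
        target <- s - 1 + (if (st[i] == 0) 2^(i - 1) else -2^(i - 1))
        ii <- c(ii, target + 1); jj <- c(jj, s); vv <- c(vv, r)
        total <- total + r
      }
    }
    if (total > 0) { ii <- c(ii, s); jj <- c(jj, s); vv <- c(vv, -total) }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n_states, n_states))
}
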