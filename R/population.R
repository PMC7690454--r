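# Population semantics: the simulation alternates free CTMC evolution over
# windows of length dt with an update phase at each window end. In the
# update phase, mass on Death=1 states is removed, mass on Division=1
# states is doubled (and Division reset to 0), the distribution is
# renormalized, the population-size factor is multiplied by
# ratio = 1 - P(Death) + P(Division & !Death), and the population-level
# parameters are recomputed from the post-update distribution. Death takes
# precedence over Division when both are set: a dead cell does not divide.

#' Empirical state distribution
#'
#' The population engine carries the cell-population state as a weighted
#' particle set: `states` is an `n x N` 0/1 matrix, `weights` sums to 1, and
#' `size` is the cumulative population-size factor (initial total = 1).
#'
#' @param states 0/1 integer matrix with one row per particle, columns named
#'   by node.
#' @param weights Particle weights (non-negative, normalized internally).
#' @param size Population-size factor.
#' @return An object of class `bp_distribution`.
#' @export
bp_distribution <- function(states, weights = NULL, size = 1) {
  if (is.null(weights)) weights <- rep(1 / nrow(states), nrow(states))
  stopifnot(length(weights) == nrow(states), all(weights >= 0), size > 0)
  weights <- weights / sum(weights)
  structure(list(states = states, weights = weights, size = size),
            class = "bp_distribution")
}

#' Node marginal probabilities of a distribution
#' @param dist A [bp_distribution()].
#' @return Named numeric vector of ON-probabilities.
#' @export
dist_marginals <- function(dist) {
  drop(crossprod(dist$states, dist$weights))
}

# weighted probability of a Boolean predicate AST over the particles
bp_dist_prob <- function(dist, ast, params) {
  v <- bp_eval_expr(ast, dist$states, params)
  sum(dist$weights * (v != 0))
}

#' One population window: propagate, then death/division update
#'
#' @param net A [bp_network()] with optional death/division nodes.
#' @param dist A [bp_distribution()] (weights normalized).
#' @param dt Window length in hours (> 0).
#' @param n_traj Number of particles resampled for the window.
#' @param seed Integer seed for this window.
#' @param params Parameter vector in force during the window (defaults to
#'   the network's).
#' @return A list with `dist` (post-update [bp_distribution()], `NULL` on
#'   extinction), `ratio` (`1 - P(Death) + P(Division & !Death)`),
#'   `p_death`, `p_division`, and `extinct`.
#' @export
population_step <- function(net, dist, dt, n_traj = nrow(dist$states),
                            seed = 1, params = NULL) {
  stopifnot(dt > 0)
  comp <- bp_compile_network(net)
  pv <- bp_param_vector(net, params)
  bp_population_step_impl(net, comp, pv, dist, dt, n_traj, seed)
}

bp_population_step_impl <- function(net, comp, pv, dist, dt, n_traj, seed) {
  # resample an equally-weighted particle set for the window
  idx <- bp_weighted_sample(dist$weights, n_traj, seed = bp_derive_seed(seed, 7))
  start <- dist$states[idx, , drop = FALSE]
  res <- bp_cpp_simulate(comp, pv, start, dt, numeric(0), as.numeric(seed),
                         FALSE, FALSE)
  states <- res$end_states
  colnames(states) <- names(net$nodes)
  w <- rep(1 / n_traj, n_traj)

  death <- if (!is.null(net$death_node)) states[, net$death_node] == 1 else rep(FALSE, n_traj)
  divide <- if (!is.null(net$division_node)) states[, net$division_node] == 1 else rep(FALSE, n_traj)
  divide <- divide & !death  # death precedence
  p_death <- sum(w[death])
  p_div <- sum(w[divide])
  ratio <- 1 - p_death + p_div

  if (ratio <= 0 || all(death))
    return(list(dist = NULL, ratio = ratio, p_death = p_death,
                p_division = p_div, extinct = TRUE))

  w[death] <- 0
  w[divide] <- 2 * w[divide]
  if (!is.null(net$division_node)) states[divide, net$division_node] <- 0L
  keep <- w > 0
  new_dist <- bp_distribution(states[keep, , drop = FALSE], w[keep],
                              size = dist$size * ratio)
  list(dist = new_dist, ratio = ratio, p_death = p_death,
       p_division = p_div, extinct = FALSE)
}

# Systematic (stratified) resampling: one uniform offset, n evenly spaced
# positions. Particle counts deviate from n * weight by at most 1, so the
# composition of the particle set does not random-walk across windows (with
# no death/division the set is carried over exactly; a particle of doubled
# weight yields exactly two copies).
bp_weighted_sample <- function(weights, n, seed) {
  u0 <- bp_rng_runif(1, seed)
  u <- (u0 + seq_len(n) - 1) / n
  findInterval(u, cumsum(weights), left.open = TRUE) + 1L
}

#' Recompute population-updated parameters from a distribution
#'
#' Each update rule is evaluated with `p(<expr>)` terms taken as weighted
#' probabilities of the predicate over the distribution's particles.
#'
#' @param net A [bp_network()] with update rules.
#' @param dist A [bp_distribution()].
#' @param params Current parameter vector (defaults to the network's).
#' @return The parameter vector with updated entries.
#' @export
update_parameters <- function(net, dist, params = NULL) {
  pv <- bp_param_vector(net, params)
  if (!length(net$update_rules)) return(pv)
  prob_fn <- function(ast) bp_dist_prob(dist, ast, pv)
  # in an update rule a bare node name stands for its population-averaged
  # ON-probability; p(<expr>) gives the joint probability of a predicate
  marg <- dist_marginals(dist)
  for (pn in names(net$update_rules)) {
    v <- bp_eval_expr(net$update_rules[[pn]], marg, pv, prob_fn = prob_fn)
    if (!is.finite(v) || v < 0)
      stop(sprintf("update rule for '$%s' produced an invalid value (%g)", pn, v),
           call. = FALSE)
    pv[[pn]] <- v
  }
  pv
}

#' Run a full population simulation
#'
#' Iterates [population_step()] and [update_parameters()], carrying the
#' end-of-window distribution into the next window and recording node
#' marginals, population size, and the trace of every updated parameter at
#' each window boundary.
#'
#' @param net A [bp_network()].
#' @param initial A [bp_initial_condition()] (or named 0/1 state).
#' @param dt Window length in hours.
#' @param n_windows Number of windows (horizon = `n_windows * dt`).
#' @param n_traj Particles per window.
#' @param seed Integer seed.
#' @param params Optional parameter overrides for the first window.
#' @param predicates Optional named list of Boolean state predicates
#'   (strings or ASTs), e.g. a cell-type map; their population
#'   probabilities are recorded at every boundary for
#'   [summarize_celltypes()].
#' @return An object of class `bp_pop_timecourse` with `time` (window
#'   boundaries, hours), `marginals` (boundary x node), `size`
#'   (population-size factor, product of per-window ratios), `ratios`,
#'   `param_trace` (boundary x updated parameter), optional `celltype_probs`,
#'   and `extinct`.
#' @export
run_population <- function(net, initial, dt, n_windows, n_traj = 1000,
                           seed = 1, params = NULL, predicates = NULL) {
  stopifnot(dt > 0, n_windows >= 1)
  if (!inherits(initial, "bp_initial_condition")) {
    st <- bp_check_state(net, initial)
    initial <- bp_initial_condition(list(prob = 1, pattern = st))
  }
  comp <- bp_compile_network(net)
  pv <- bp_param_vector(net, params)
  preds <- lapply(predicates, bp_as_ast)

  start <- bp_sample_initial(net, initial, n_traj, seed = bp_derive_seed(seed, 3))
  dist <- bp_distribution(start)

  nb <- n_windows + 1L
  nn <- names(net$nodes)
  marg <- matrix(NA_real_, nb, length(nn), dimnames = list(NULL, nn))
  size <- rep(NA_real_, nb)
  ratios <- rep(NA_real_, nb)
  upd_names <- names(net$update_rules)
  ptrace <- matrix(NA_real_, nb, length(upd_names),
                   dimnames = list(NULL, upd_names))
  ct <- if (length(preds)) matrix(NA_real_, nb, length(preds),
                                  dimnames = list(NULL, names(preds))) else NULL

  record <- function(b, dist, pv, ratio) {
    marg[b, ] <<- dist_marginals(dist)
    size[b] <<- dist$size
    ratios[b] <<- ratio
    if (length(upd_names)) ptrace[b, ] <<- pv[upd_names]
    if (length(preds))
      ct[b, ] <<- vapply(preds, function(a) bp_dist_prob(dist, a, pv), numeric(1))
  }
  record(1L, dist, pv, 1)

  extinct <- FALSE
  last <- nb
  for (w in seq_len(n_windows)) {
    stp <- bp_population_step_impl(net, comp, pv, dist, dt, n_traj,
                                   seed = bp_derive_seed(seed, 100 + w))
    if (stp$extinct) {
      extinct <- TRUE
      last <- w  # boundaries 1..w recorded
      warning(sprintf("population extinct in window %d (ratio = %g)", w, stp$ratio),
              call. = FALSE)
      break
    }
    dist <- stp$dist
    pv <- update_parameters(net, dist, pv)
    record(w + 1L, dist, pv, stp$ratio)
    last <- w + 1L
  }

  keep <- seq_len(last)
  structure(list(time = (keep - 1L) * dt,
                 marginals = marg[keep, , drop = FALSE],
                 size = size[keep],
                 ratios = ratios[keep],
                 param_trace = ptrace[keep, , drop = FALSE],
                 celltype_probs = if (!is.null(ct)) ct[keep, , drop = FALSE],
                 dt = dt, n_traj = n_traj, seed = seed,
                 extinct = extinct,
                 final_dist = dist, final_params = pv),
            class = "bp_pop_timecourse")
}

#' @export
print.bp_pop_timecourse <- function(x, ...) {
  cat(sprintf("Population timecourse: %d boundaries, dt = %g h, %d particles%s\n",
              length(x$time), x$dt, x$n_traj,
              if (x$extinct) " (extinct)" else ""))
  cat(sprintf("  final population size factor: %.4g\n", x$size[length(x$size)]))
  invisible(x)
}

#' Tidy data frame of a population timecourse
#'
#' @param x A `bp_pop_timecourse`.
#' @param ... Unused.
#' @return Data frame with columns `window_time`, `quantity`
#'   (`node:<name>`, `param:<name>`, `celltype:<name>` or
#'   `population_size`) and `value`.
#' @export
as.data.frame.bp_pop_timecourse <- function(x, ...) {
  blocks <- list(
    data.frame(window_time = x$time, quantity = "population_size",
               value = x$size, stringsAsFactors = FALSE))
  add <- function(mat, prefix) {
    if (is.null(mat) || !ncol(mat)) return()
    blocks[[length(blocks) + 1L]] <<- data.frame(
      window_time = rep(x$time, ncol(mat)),
      quantity = paste0(prefix, rep(colnames(mat), each = nrow(mat))),
      value = as.vector(mat), stringsAsFactors = FALSE)
  }
  add(x$marginals, "node:")
  add(x$param_trace, "param:")
  add(x$celltype_probs, "celltype:")
  do.call(rbind, blocks)
}
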