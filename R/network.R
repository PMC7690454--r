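#' Construct a node specification
#'
#' A node of a rate-annotated Boolean network carries two transition-rate
#' expressions: `rate_up` applies while the node is 0 (activation), and
#' `rate_down` while it is 1 (inactivation). Rates are in 1/h; the mean
#' waiting time of a transition with constant rate `k` is `1/k` hours.
#'
#' @param name Node identifier (letters, digits, underscore; must not start
#'   with a digit).
#' @param rate_up,rate_down Rate expressions: a string in the model dialect
#'   (e.g. `"(A & !B) ? $k : 0"`), a single number, or a parsed expression.
#' @return An object of class `bp_node`.
#' @export
bp_node <- function(name, rate_up = 0, rate_down = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", name))
    stop(sprintf("invalid node name '%s'", name), call. = FALSE)
  structure(list(name = name,
                 rate_up = bp_as_ast(rate_up),
                 rate_down = bp_as_ast(rate_down)),
            class = "bp_node")
}

#' Construct a Boolean network
#'
#' @param nodes List of [bp_node()] specifications (unique names).
#' @param params Named numeric vector of `$`-parameters (non-negative).
#' @param death,division Optional names of the Death and Division nodes used
#'   by the population engine.
#' @param update_rules Named list mapping a parameter name to an update-rule
#'   expression evaluated at the population level at the end of every
#'   simulation window. Update rules may use `p(<boolean expression>)`, the
#'   population probability of a state predicate, alongside parameters.
#' @return An object of class `bp_network`.
#' @export
bp_network <- function(nodes, params = numeric(0), death = NULL,
                       division = NULL, update_rules = list()) {
  names_ <- vapply(nodes, function(x) x$name, character(1))
  if (anyDuplicated(names_))
    stop("duplicate node names: ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "), call. = FALSE)
  names(nodes) <- names_
  if (length(params)) {
    if (is.null(names(params)) || any(names(params) == ""))
      stop("parameters must be named", call. = FALSE)
    if (any(!is.finite(params)) || any(params < 0))
      stop("parameter values must be finite and non-negative", call. = FALSE)
  }
  if (!is.null(death) && !is.null(division) && identical(death, division))
    stop("death node and division node must differ", call. = FALSE)
  for (nd in c(death, division))
    if (!is.null(nd) && !nd %in% names_)
      stop(sprintf("node '%s' is not part of the network", nd), call. = FALSE)
  ur <- lapply(update_rules, bp_as_ast, allow_prob = TRUE)
  net <- structure(list(nodes = nodes, params = params, death_node = death,
                        division_node = division, update_rules = ur),
                   class = "bp_network")
  bp_validate_network(net)
  net
}

bp_validate_network <- function(net) {
  node_names <- names(net$nodes)
  param_names <- names(net$params)
  check_syms <- function(ast, where) {
    syms <- bp_expr_symbols(ast)
    bad_n <- setdiff(syms$nodes, node_names)
    if (length(bad_n))
      stop(sprintf("undeclared identifier '%s' in %s", bad_n[1], where), call. = FALSE)
    bad_p <- setdiff(syms$params, param_names)
    if (length(bad_p))
      stop(sprintf("undeclared parameter '$%s' in %s", bad_p[1], where), call. = FALSE)
  }
  for (nd in net$nodes) {
    check_syms(nd$rate_up, sprintf("rate_up of node '%s'", nd$name))
    check_syms(nd$rate_down, sprintf("rate_down of node '%s'", nd$name))
  }
  for (pn in names(net$update_rules)) {
    if (!pn %in% param_names)
      stop(sprintf("update rule targets undeclared parameter '$%s'", pn), call. = FALSE)
    check_syms(net$update_rules[[pn]], sprintf("update rule for '$%s'", pn))
  }
  invisible(net)
}

#' @export
print.bp_network <- function(x, ...) {
  cat(sprintf("Boolean network: %d nodes, %d parameters", length(x$nodes),
              length(x$params)))
  if (length(x$update_rules))
    cat(sprintf(", %d population-updated", length(x$update_rules)))
  cat("\n")
  if (!is.null(x$death_node))
    cat(sprintf("  death node: %s; division node: %s\n", x$death_node,
                if (is.null(x$division_node)) "<none>" else x$division_node))
  invisible(x)
}

#' Number of nodes in a network
#' @param net A [bp_network()].
#' @return Integer node count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' Names of the network's nodes
#' @param net A [bp_network()].
#' @return Character vector in network order.
#' @export
node_names <- function(net) names(net$nodes)

#' Evaluate the active transition rate of a node in a given state
#'
#' Returns the value of the node's `rate_up` expression if the node is 0 in
#' `state`, and of `rate_down` if it is 1.
#'
#' @param net A [bp_network()].
#' @param node Node name.
#' @param state Named 0/1 vector covering all nodes of the network.
#' @param params Parameter values; defaults to the network's own.
#' @return A non-negative rate (1/h).
#' @export
evaluate_rate <- function(net, node, state, params = net$params) {
  if (!node %in% names(net$nodes))
    stop(sprintf("unknown node '%s'", node), call. = FALSE)
  state <- bp_check_state(net, state)
  nd <- net$nodes[[node]]
  expr <- if (state[[node]] == 0) nd$rate_up else nd$rate_down
  r <- bp_eval_expr(expr, state, params)
  if (!is.finite(r) || r < 0)
    stop(sprintf("rate expression for node '%s' evaluated to an invalid value (%g)",
                 node, r), call. = FALSE)
  r
}

bp_check_state <- function(net, state) {
  nn <- names(net$nodes)
  if (is.null(names(state))) {
    if (length(state) != length(nn))
      stop("state length does not match the number of nodes", call. = FALSE)
    names(state) <- nn
  }
  missing <- setdiff(nn, names(state))
  if (length(missing))
    stop("state is missing nodes: ", paste(missing, collapse = ", "), call. = FALSE)
  if (!all(state[nn] %in% c(0, 1)))
    stop("state values must be 0 or 1", call. = FALSE)
  state[nn]
}

#' Enumerate the state space of a network
#'
#' States are encoded as integers in `[0, 2^N)`: bit `i - 1` of the code is
#' the value of the `i`-th node in network order.
#'
#' @param net A [bp_network()].
#' @param cap Largest node count for which full enumeration is performed.
#' @return A list with `count` (`2^N`) and, when `N <= cap`, `states`
#'   (a `2^N x N` 0/1 matrix, row `k` decoding integer `k - 1`); above the
#'   cap `states` is `NULL` and only the count is reported.
#' @export
enumerate_states <- function(net, cap = 20) {
  N <- n_nodes(net)
  count <- 2^N
  states <- NULL
  if (N <= cap) {
    codes <- 0:(count - 1)
    states <- vapply(seq_len(N), function(i) bitwAnd(codes %/% 2^(i - 1), 1L),
                     integer(count))
    states <- matrix(as.integer(states), nrow = count, ncol = N,
                     dimnames = list(NULL, names(net$nodes)))
  }
  list(count = count, states = states)
}

#' Encode a network state as an integer
#' @param state Named (or network-ordered) 0/1 vector.
#' @param net The network giving the node order.
#' @return Integer code in `[0, 2^N)`.
#' @export
encode_state <- function(net, state) {
  state <- bp_check_state(net, state)
  N <- length(state)
  if (N > 30) stop("integer state encoding supported for at most 30 nodes", call. = FALSE)
  sum(state * 2^(seq_len(N) - 1))
}

#' Decode an integer state code
#' @param net The network giving the node order.
#' @param code Integer in `[0, 2^N)`.
#' @return Named 0/1 vector.
#' @export
decode_state <- function(net, code) {
  N <- n_nodes(net)
  bits <- as.integer(bitwAnd(code %/% 2^(seq_len(N) - 1), 1L))
  names(bits) <- names(net$nodes)
  bits
}

# --- initial conditions ------------------------------------------------------

#' Initial condition over network states
#'
#' A mixture of state patterns. Each pattern fixes some nodes to 0/1 and may
#' leave others as wildcards (`NA`); a pattern's mass is spread uniformly
#' over all matching states. Nodes absent from a pattern are fixed at 0.
#'
#' @param ... Pattern components, each a `list(prob = , pattern = )` where
#'   `pattern` is a named vector with values 0, 1 or `NA` (wildcard).
#' @return An object of class `bp_initial_condition`.
#' @export
bp_initial_condition <- function(...) {
  atoms <- list(...)
  if (length(atoms) == 1L && is.null(atoms[[1]]$prob)) atoms <- atoms[[1]]
  probs <- vapply(atoms, function(a) a$prob, numeric(1))
  if (any(probs < 0)) stop("initial-condition masses must be non-negative", call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-9)
    stop(sprintf("initial-condition masses must sum to 1 (got %g)", sum(probs)),
         call. = FALSE)
  structure(list(atoms = atoms), class = "bp_initial_condition")
}

# Expand an initial condition into an explicit distribution over the full
# state space (small N only). Returns a numeric vector of length 2^N indexed
# by state code + 1.
bp_expand_initial <- function(net, init, cap = 20) {
  N <- n_nodes(net)
  if (N > cap) stop("explicit expansion requires at most ", cap, " nodes", call. = FALSE)
  nn <- names(net$nodes)
  p <- numeric(2^N)
  for (a in init$atoms) {
    pat <- a$pattern
    bad <- setdiff(names(pat), nn)
    if (length(bad))
      stop(sprintf("initial condition references unknown node '%s'", bad[1]), call. = FALSE)
    fixed <- rep(0L, N)
    names(fixed) <- nn
    wild <- rep(FALSE, N)
    names(wild) <- nn
    fixed[names(pat)[!is.na(pat)]] <- as.integer(pat[!is.na(pat)])
    wild[names(pat)[is.na(pat)]] <- TRUE
    wild_idx <- which(wild)
    n_match <- 2^length(wild_idx)
    share <- a$prob / n_match
    combos <- if (length(wild_idx)) expand.grid(rep(list(0:1), length(wild_idx))) else NULL
    for (k in seq_len(n_match)) {
      s <- fixed
      if (length(wild_idx)) s[wild_idx] <- as.integer(combos[k, ])
      code <- sum(s * 2^(seq_len(N) - 1))
      p[code + 1] <- p[code + 1] + share
    }
  }
  p
}

# Sample start states (n x N 0/1 integer matrix) from an initial condition.
# Uses its own deterministic generator so the caller's RNG is untouched.
bp_sample_initial <- function(net, init, n, seed) {
  nn <- names(net$nodes)
  N <- length(nn)
  probs <- vapply(init$atoms, function(a) a$prob, numeric(1))
  rs <- bp_rng_runif(1 + N * n, seed)
  # stratified allocation over the mixture atoms: realized counts deviate
  # from n * prob by at most 1
  u <- (rs[1] + seq_len(n) - 1) / n
  pick <- findInterval(u, cumsum(probs), left.open = TRUE) + 1L
  pick[pick > length(probs)] <- length(probs)
  out <- matrix(0L, n, N, dimnames = list(NULL, nn))
  uw <- matrix(rs[-1], n, N)
  for (j in seq_along(init$atoms)) {
    rows <- which(pick == j)
    if (!length(rows)) next
    pat <- init$atoms[[j]]$pattern
    fixed <- names(pat)[!is.na(pat)]
    out[rows, fixed] <- matrix(as.integer(pat[fixed]), length(rows),
                               length(fixed), byrow = TRUE)
    wilds <- names(pat)[is.na(pat)]
    if (length(wilds))
      out[rows, wilds] <- (uw[rows, match(wilds, nn), drop = FALSE] < 0.5) * 1L
  }
  out
}

# Deterministic uniform stream independent of R's global RNG.
bp_rng_runif <- function(n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  stats::runif(n)
}

# --- compilation for the C++ kernel ------------------------------------------

bp_compile_network <- function(net) {
  nn <- names(net$nodes)
  pn <- names(net$params)
  node_index <- as.list(stats::setNames(seq_along(nn), nn))
  param_index <- as.list(stats::setNames(seq_along(pn), pn))
  up <- vector("list", length(nn))
  down <- vector("list", length(nn))
  # deps[j]: 0-based indices of nodes whose active rate can change when node
  # j flips (any node referencing j, plus j itself since its own expression
  # switches between rate_up and rate_down)
  dep_sets <- lapply(seq_along(nn), function(i) i)
  for (i in seq_along(nn)) {
    nd <- net$nodes[[i]]
    up[[i]] <- bp_compile_expr(nd$rate_up, node_index, param_index)
    down[[i]] <- bp_compile_expr(nd$rate_down, node_index, param_index)
    refs <- union(bp_expr_symbols(nd$rate_up)$nodes,
                  bp_expr_symbols(nd$rate_down)$nodes)
    for (r in refs) {
      j <- node_index[[r]]
      dep_sets[[j]] <- union(dep_sets[[j]], i)
    }
  }
  list(n = length(nn), names = nn, up = up, down = down,
       deps = lapply(dep_sets, function(d) as.integer(sort(d) - 1L)),
       param_names = pn)
}

bp_param_vector <- function(net, params = NULL) {
  p <- net$params
  if (!is.null(params)) p[names(params)] <- params
  p
}
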