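# Small networks used across test files.

one_node_net <- function(k = 0.25) {
  bp_network(list(bp_node("A", rate_up = "$k")), params = c(k = k))
}

two_indep_net <- function(k1 = 0.25, k2 = 0.5) {
  bp_network(list(bp_node("A", rate_up = "$k1"), bp_node("B", rate_up = "$k2")),
             params = c(k1 = k1, k2 = k2))
}

# state helper: named 0/1 vector over a network's nodes, default all 0
net_state <- function(net, on = character(0)) {
  s <- stats::setNames(rep(0, n_nodes(net)), node_names(net))
  s[on] <- 1
  s
}

# canonical serialized form, for semantic model comparison
model_fingerprint <- function(network, initial = NULL, settings = numeric(0)) {
  write_model(network, initial, settings)
}
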