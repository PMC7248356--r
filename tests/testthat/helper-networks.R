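# Fixtures built in code: small reference networks and a random stable
# network generator used across the suite.

# Single neuron with no outgoing weights: q = Lambda / (r_sink + lambda).
isolated_neuron <- function(r_sink = 2) {
  gnetwork(matrix(0, 1, 1), matrix(0, 1, 1), r_sink = r_sink,
           field_label = "OUT")
}

# Two-neuron feedforward chain: Lambda1 -> n1 -(w+)-> n2 (sink).
two_neuron_chain <- function(w = 1, r_sink2 = 1) {
  wp <- matrix(c(0, w, 0, 0), 2, 2, byrow = TRUE)
  gnetwork(wp, matrix(0, 2, 2), d = 0, r_sink = c(NA, r_sink2),
           field_label = c("CAN", "OUT"))
}

# Random stable network: modest weights and arrivals; rejection-sample
# (deterministically, from the seed) until the fixed point sits well inside
# the product-form regime.
random_stable_network <- function(n = 4, seed = 1, excitatory_only = FALSE,
                                  max_q = 0.9) {
  for (k in 0:99) {
    set.seed(seed + 100000 * k)
    wp <- matrix(runif(n * n) * 0.3, n, n)
    wm <- matrix(runif(n * n) * 0.3, n, n)
    if (excitatory_only) wm[] <- 0
    diag(wp) <- diag(wm) <- 0
    wp[n, ] <- 0
    wm[n, ] <- 0   # last neuron is the output sink
    net <- gnetwork(wp, wm, d = runif(n) * 0.3,
                    r_sink = c(rep(NA_real_, n - 1), 1 + runif(1)),
                    field_label = c(rep("CAN", n - 1), "OUT"))
    arrivals <- external_arrivals(Lambda = runif(n) * 0.5,
                                  lambda_minus = runif(n) * 0.3, n = n)
    q <- tryCatch(solve_steady_state(net, arrivals)$q,
                  error = function(e) NULL)
    if (!is.null(q) && all(q <= max_q))
      return(list(net = net, arrivals = arrivals))
  }
  stop("no stable network found for this seed")
}

# Tiny three-neuron chain RF -> CAN -> OUT used for learning convergence.
three_neuron_chain <- function(seed = 1) {
  cfg <- cann_config(n_streams = 1, n_layers = 1, n_rf_inputs = 1,
                     n_lcf_inputs = 0, n_ucf_units = 0,
                     cans_per_stream_layer = 1, seed = seed)
  build_cann(cfg)
}
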