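#' Simulate a G-network as a continuous-time Markov chain
#'
#' Exact event-driven simulation with competing exponential clocks: external
#' positive/negative Poisson arrivals per neuron and firing of every neuron
#' whose potential is positive. A firing neuron decrements its own potential
#' and, according to the transition probabilities, sends a +1 or -1 impulse
#' to a target (negative impulses floor potentials at zero) or departs the
#' network. The run terminates after `n_events` events, which makes it
#' reproducible event-for-event given the seed.
#'
#' This simulator is deliberately independent of [solve_steady_state()]; the
#' time-weighted activation frequencies it returns converge to the
#' fixed-point excitation probabilities `q` and serve as an oracle for them.
#'
#' @param net a `gnetwork`.
#' @param arrivals an [external_arrivals()] object.
#' @param n_events number of simulated events (>= 1).
#' @param seed integer seed; the run is fully reproducible.
#' @param hist_cap if non-`NULL`, also accumulate the time-weighted joint
#'   state histogram with potentials clipped at `hist_cap` (only sensible
#'   for small networks).
#'
#' @return An object of class `gnet_simulation`: `activation` (per-neuron
#'   fraction of time with positive potential), `n_touched` (events that
#'   addressed each neuron), `std_error` (binomial-style standard error
#'   `sqrt(p(1-p)/n_touched)` — each event touching a neuron is one
#'   observation of its state process), `total_time`, `n_events`, and
#'   `state_hist` (an n-dimensional array of occupancy probabilities) when
#'   `hist_cap` is given.
#' @export
#' @examples
#' net <- gnetwork(matrix(0, 1, 1), matrix(0, 1, 1), r_sink = 2)
#' sim <- simulate_network(net, external_arrivals(Lambda = 1, n = 1),
#'                         n_events = 1e4, seed = 1)
#' sim$activation  # close to 0.5
simulate_network <- function(net, arrivals, n_events, seed,
                             hist_cap = NULL) {
  stopifnot(n_events >= 1)
  r <- firing_rates(net)
  p <- transition_probabilities(net)
  if (sum(arrivals$Lambda) + sum(arrivals$lambda_minus) + sum(r) <= 0)
    stop("degenerate simulation: all event rates are zero")
  cap <- if (is.null(hist_cap)) -1L else as.integer(hist_cap)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  res <- .simulate_gnet_cpp(p$p_plus, p$p_minus, net$d, r,
                            arrivals$Lambda, arrivals$lambda_minus,
                            as.numeric(n_events), cap)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  act <- res$activation
  out <- list(activation = act, n_touched = res$n_touched,
              std_error = sqrt(pmax(act * (1 - act), 0) /
                                 pmax(res$n_touched, 1)),
              total_time = res$total_time, n_events = res$n_events,
              seed = as.integer(seed))
  if (cap >= 0) {
    h <- array(res$state_hist, dim = rep(cap + 1L, net$n_neurons))
    out$state_hist <- h / sum(h)
  }
  structure(out, class = "gnet_simulation")
}

#' @export
print.gnet_simulation <- function(x, ...) {
  cat("G-network CTMC simulation:", format(x$n_events, big.mark = ","),
      "events over", format(x$total_time, digits = 4), "time units\n")
  print(round(x$activation, 4))
  invisible(x)
}
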