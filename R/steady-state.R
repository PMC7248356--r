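#' Solve the product-form steady state of a G-network
#'
#' The excitation probability of each neuron satisfies the nonlinear network
#' equations
#' \deqn{q_i = \frac{\Lambda_i + \sum_j q_j w^+(j,i)}
#'                  {r_i + \lambda_i + \sum_j q_j w^-(j,i)}}
#' where \eqn{r_i} is the firing rate. The numerator is the aggregate
#' positive-signal rate `Q+` and the denominator minus `r` the aggregate
#' negative-signal rate `Q-`. The fixed point is found by damped successive
#' substitution from `q = 0`: the map is monotone from below, and damping
#' avoids oscillation. Values are clipped into `[0, 1]` during iteration; a
#' fixed point with any `q_i >= 1 - 1e-9` is outside the product-form regime
#' and raises a saturation error rather than being silently clipped.
#'
#' @param net a `gnetwork`.
#' @param arrivals an [external_arrivals()] object.
#' @param tol convergence tolerance on the unrelaxed residual
#'   `max |T(q) - q|`.
#' @param max_iter maximum number of iterations.
#' @param damping relaxation factor in `(0, 1]`; 0.5 by default.
#' @param q_init optional warm-start vector (defaults to zero).
#' @param check validate the network before solving (disabled by the
#'   training loop, which keeps the network valid by construction).
#' @param on_saturation `"error"` (default) raises the instability error;
#'   `"clip"` returns the clipped fixed point with `saturated = TRUE`
#'   instead — the physically sensible limit for prediction, since an
#'   unstable neuron's activation fraction tends to one.
#'
#' @return An object of class `gnet_steady_state`: list with `q`, `Q_plus`,
#'   `Q_minus`, `converged`, `n_iterations`, `residual`.
#' @export
#' @examples
#' net <- gnetwork(matrix(0, 1, 1), matrix(0, 1, 1), r_sink = 2)
#' ss <- solve_steady_state(net, external_arrivals(Lambda = 1, n = 1))
#' ss$q  # 1 / 2
solve_steady_state <- function(net, arrivals, tol = 1e-10, max_iter = 10000,
                               damping = 0.5, q_init = NULL, check = TRUE,
                               on_saturation = c("error", "clip")) {
  stopifnot(tol > 0, max_iter >= 1, damping > 0, damping <= 1)
  on_saturation <- match.arg(on_saturation)
  r <- if (check) firing_rates(net) else firing_rates_raw(net)
  n <- net$n_neurons
  stopifnot(length(arrivals$Lambda) == n)
  q <- if (is.null(q_init)) numeric(n) else pmin(pmax(q_init, 0), 1)
  fp <- .gnet_fixed_point_cpp(net$w_plus, net$w_minus, r, arrivals$Lambda,
                              arrivals$lambda_minus, q, tol,
                              as.integer(max_iter), damping)
  q <- fp$q
  converged <- fp$converged
  res <- fp$residual
  it <- fp$n_iterations
  if (!converged)
    stop(sprintf(
      "steady state did not converge in %d iterations (residual %.3g)",
      max_iter, res))
  saturated <- any(q >= 1 - 1e-9)
  if (saturated && on_saturation == "error") {
    bad <- which(q >= 1 - 1e-9)
    stop(structure(class = c("gnet_saturation", "error", "condition"),
                   list(message = paste0(
                     "saturation: excitation probability reached 1 for ",
                     "neuron(s) ", paste(bad, collapse = ", "),
                     "; network is not in the product-form regime"),
                     call = sys.call(-1), neurons = bad)))
  }
  Q_plus <- arrivals$Lambda + drop(crossprod(net$w_plus, q))
  Q_minus <- arrivals$lambda_minus + drop(crossprod(net$w_minus, q))
  structure(list(q = q, Q_plus = Q_plus, Q_minus = Q_minus,
                 converged = converged, n_iterations = it, residual = res,
                 saturated = saturated),
            class = "gnet_steady_state")
}

#' @export
print.gnet_steady_state <- function(x, ...) {
  cat("G-network steady state (", length(x$q), " neurons, ",
      x$n_iterations, " iterations, residual ",
      format(x$residual, digits = 3), ")\n", sep = "")
  print(round(x$q, 4))
  invisible(x)
}

#' Stationary probability of a joint potential state
#'
#' Under the product-form property the stationary distribution of the joint
#' potential vector factorizes over neurons as geometric marginals:
#' \deqn{P(k) = \prod_y (1 - q_y) q_y^{k_y}.}
#'
#' @param ss a converged `gnet_steady_state`.
#' @param state vector of non-negative integer neuron potentials.
#' @return The stationary probability of `state`.
#' @export
stationary_probability <- function(ss, state) {
  stopifnot(inherits(ss, "gnet_steady_state"))
  if (!isTRUE(ss$converged)) stop("steady state is not converged")
  state <- as.numeric(state)
  if (length(state) != length(ss$q) || any(state < 0) ||
      any(state != round(state)))
    stop("state must be length-n non-negative integers")
  prod((1 - ss$q) * ss$q^state)
}

#' Per-neuron steady-state report
#'
#' One row per neuron: field label, excitation probability, aggregate signal
#' rates, and (optionally) empirical activation and standard error from a
#' simulation run. Suitable for writing with [utils::write.csv()].
#'
#' @param net a `gnetwork`.
#' @param ss a `gnet_steady_state`.
#' @param sim optional result of [simulate_network()].
#' @return A `data.frame`.
#' @export
steady_state_report <- function(net, ss, sim = NULL) {
  out <- data.frame(
    neuron = seq_len(net$n_neurons), label = net$field_label,
    q = ss$q, Q_plus = ss$Q_plus, Q_minus = ss$Q_minus)
  if (!is.null(sim)) {
    out$empirical_activation <- sim$activation
    out$std_error <- sim$std_error
  }
  out
}
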