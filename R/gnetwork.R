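#' Construct a G-network (random neural network)
#'
#' A G-network is a network of spiking units that exchange excitatory (+1) and
#' inhibitory (-1) impulses at Poisson rates. Each directed edge `i -> j`
#' carries a non-negative excitatory rate weight `w+(i,j)` and an inhibitory
#' rate weight `w-(i,j)` (events per unit time). When a neuron with positive
#' potential fires, the impulse either reaches another neuron or leaves the
#' network ("departs") with probability `d(i)`. Neurons with no outgoing
#' weights ("sinks", e.g. output neurons) need an explicit firing rate
#' `r_sink`, because the usual rate formula is 0/0 for them.
#'
#' @param w_plus n x n matrix of non-negative excitatory rate weights; entry
#'   `[i, j]` is the rate of positive impulses from neuron `i` to neuron `j`.
#' @param w_minus n x n matrix of non-negative inhibitory rate weights.
#' @param d length-n vector of departure probabilities in `[0, 1]` (recycled
#'   from a scalar). Neurons with outgoing weight mass must have `d < 1`.
#' @param r_sink optional length-n vector of explicit firing rates for sink
#'   neurons (ignored for neurons with outgoing weights). May contain `NA`
#'   for non-sink neurons.
#' @param field_label length-n character vector with values from
#'   `c("RF", "LCF", "UCF", "CAN", "OUT")`; defaults to `"CAN"`.
#'
#' @return An object of class `gnetwork`.
#' @seealso [firing_rates()], [solve_steady_state()], [simulate_network()]
#' @export
#' @examples
#' net <- gnetwork(w_plus = matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE),
#'                 w_minus = matrix(0, 2, 2),
#'                 d = c(0, 0), r_sink = c(NA, 1),
#'                 field_label = c("RF", "OUT"))
#' firing_rates(net)
gnetwork <- function(w_plus, w_minus, d = 0, r_sink = NULL,
                     field_label = NULL) {
  w_plus <- as.matrix(w_plus)
  w_minus <- as.matrix(w_minus)
  n <- nrow(w_plus)
  d <- rep_len(as.numeric(d), n)
  if (is.null(r_sink)) r_sink <- rep(NA_real_, n)
  r_sink <- rep_len(as.numeric(r_sink), n)
  if (is.null(field_label)) field_label <- rep("CAN", n)
  net <- structure(
    list(n_neurons = n, w_plus = w_plus, w_minus = w_minus, d = d,
         r_sink = r_sink, field_label = as.character(field_label)),
    class = "gnetwork")
  validate_gnetwork(net)
  net
}

gnet_fields <- c("RF", "LCF", "UCF", "CAN", "OUT")

#' Validate a G-network
#'
#' Checks the structural invariants: square non-negative weight matrices with
#' zero diagonal (self-loops are forbidden), departure probabilities in
#' `[0, 1]` with `d < 1` wherever a neuron has outgoing weight mass, and
#' recognised field labels.
#'
#' @param net a `gnetwork` object.
#' @return `net`, invisibly; errors on violation.
#' @export
validate_gnetwork <- function(net) {
  stopifnot(inherits(net, "gnetwork"))
  n <- net$n_neurons
  for (nm in c("w_plus", "w_minus")) {
    w <- net[[nm]]
    if (!is.matrix(w) || nrow(w) != n || ncol(w) != n)
      stop(nm, " must be a ", n, "x", n, " matrix")
    if (any(!is.finite(w)) || any(w < 0))
      stop(nm, " must be finite and non-negative")
    if (any(diag(w) != 0))
      stop("self-loops are forbidden: diagonal of ", nm, " must be zero")
  }
  if (length(net$d) != n || any(!is.finite(net$d)) ||
      any(net$d < 0) || any(net$d > 1))
    stop("d must be length-", n, " with entries in [0, 1]")
  out_mass <- rowSums(net$w_plus) + rowSums(net$w_minus)
  if (any(net$d[out_mass > 0] >= 1))
    stop("inconsistent network: d(i) = 1 for a neuron with outgoing weights")
  if (!all(net$field_label %in% gnet_fields))
    stop("field_label entries must be one of: ",
         paste(gnet_fields, collapse = ", "))
  invisible(net)
}

#' @export
print.gnetwork <- function(x, ...) {
  out_mass <- rowSums(x$w_plus) + rowSums(x$w_minus)
  cat("G-network with", x$n_neurons, "neurons\n")
  cat("  fields:",
      paste(sprintf("%s=%d", names(table(x$field_label)),
                    table(x$field_label)), collapse = " "), "\n")
  cat("  edges: ", sum(x$w_plus > 0), " excitatory, ",
      sum(x$w_minus > 0), " inhibitory; ", sum(out_mass == 0),
      " sink neuron(s)\n", sep = "")
  invisible(x)
}

#' External Poisson arrival rates
#'
#' Exogenous signals reach neurons from outside the network as independent
#' Poisson streams: rate `Lambda` for excitatory (+1) impulses and
#' `lambda_minus` for inhibitory (-1) impulses.
#'
#' @param Lambda length-n non-negative excitatory arrival rates.
#' @param lambda_minus length-n non-negative inhibitory arrival rates.
#' @param n number of neurons (for recycling scalars).
#' @return An object of class `external_arrivals`.
#' @export
external_arrivals <- function(Lambda = 0, lambda_minus = 0, n = NULL) {
  if (is.null(n)) n <- max(length(Lambda), length(lambda_minus))
  Lambda <- rep_len(as.numeric(Lambda), n)
  lambda_minus <- rep_len(as.numeric(lambda_minus), n)
  if (any(!is.finite(Lambda)) || any(Lambda < 0) ||
      any(!is.finite(lambda_minus)) || any(lambda_minus < 0))
    stop("arrival rates must be finite and non-negative")
  structure(list(Lambda = Lambda, lambda_minus = lambda_minus),
            class = "external_arrivals")
}

is_sink <- function(net) {
  rowSums(net$w_plus) + rowSums(net$w_minus) == 0
}

# firing rates without re-validating the network; hot path for training
firing_rates_raw <- function(net) {
  out_mass <- rowSums(net$w_plus) + rowSums(net$w_minus)
  sink <- out_mass == 0
  r <- out_mass / (1 - net$d)
  r[sink] <- net$r_sink[sink]
  r
}

#' Firing rates of a G-network
#'
#' For a neuron with outgoing weights the firing rate is the total outgoing
#' rate mass inflated by the departure probability,
#' `r_i = (1 - d_i)^(-1) * sum_j (w+(i,j) + w-(i,j))`. Sink neurons have no
#' outgoing mass and use their explicit `r_sink` rate.
#'
#' @param net a `gnetwork`.
#' @return Length-n vector of non-negative firing rates.
#' @export
firing_rates <- function(net) {
  validate_gnetwork(net)
  out_mass <- rowSums(net$w_plus) + rowSums(net$w_minus)
  sink <- out_mass == 0
  r <- numeric(net$n_neurons)
  r[!sink] <- out_mass[!sink] / (1 - net$d[!sink])
  if (any(sink & is.na(net$r_sink)))
    stop("missing parameter: sink neuron(s) ",
         paste(which(sink & is.na(net$r_sink)), collapse = ", "),
         " have no r_sink")
  r[sink] <- net$r_sink[sink]
  if (any(!is.finite(r)) || any(r < 0))
    stop("inconsistent network: firing rates must be finite and non-negative")
  r
}

#' Transition probabilities implied by the rate weights
#'
#' Each weight is the firing rate times a routing probability,
#' `w+-(i,j) = r_i * p+-(i,j)`, so the probabilities are recovered as
#' `p+-(i,j) = w+-(i,j) / r_i`. Sink neurons have all-zero rows (their
#' impulses always depart).
#'
#' @param net a `gnetwork`.
#' @return List with matrices `p_plus` and `p_minus`.
#' @export
transition_probabilities <- function(net) {
  r <- firing_rates(net)
  sink <- is_sink(net)
  if (any(!sink & r == 0))
    stop("division undefined: zero firing rate with positive outgoing weights")
  scale <- ifelse(sink, 0, 1 / ifelse(r == 0, 1, r))
  list(p_plus = net$w_plus * scale, p_minus = net$w_minus * scale)
}

#' Probability-conservation diagnostic
#'
#' For every neuron, the departure probability plus all outgoing excitatory
#' and inhibitory routing probabilities must total one:
#' `d(i) + sum_j (p+(i,j) + p-(i,j)) = 1`. For sink neurons the departure
#' probability is effectively one. This function returns the per-neuron sum;
#' [is_conservative()] asserts it equals 1 within `tol`.
#'
#' @param net a `gnetwork`.
#' @return Length-n numeric vector of per-neuron sums.
#' @export
check_conservation <- function(net) {
  p <- transition_probabilities(net)
  sink <- is_sink(net)
  d_eff <- ifelse(sink, 1, net$d)
  d_eff + rowSums(p$p_plus) + rowSums(p$p_minus)
}

#' @rdname check_conservation
#' @param tol numeric tolerance.
#' @return `is_conservative()`: logical scalar.
#' @export
is_conservative <- function(net, tol = 1e-12) {
  all(abs(check_conservation(net) - 1) <= tol)
}

#' Write / read a G-network as JSON
#'
#' Serializes the network with row-major weight matrices, full double
#' precision and a format-version key; the round trip is bit exact.
#'
#' @param net a `gnetwork`.
#' @param path file path.
#' @return `write_gnetwork()`: `path` invisibly. `read_gnetwork()`: a
#'   `gnetwork`.
#' @export
write_gnetwork <- function(net, path) {
  validate_gnetwork(net)
  doc <- list(
    format = "cannets-gnetwork", version = 1L,
    n_neurons = net$n_neurons,
    w_plus = as.vector(t(net$w_plus)),   # row-major
    w_minus = as.vector(t(net$w_minus)),
    d = net$d, r_sink = net$r_sink, field_label = net$field_label)
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_gnetwork
#' @export
read_gnetwork <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "cannets-gnetwork"))
    stop("not a cannets G-network JSON file")
  n <- as.integer(doc$n_neurons)
  r_sink <- as.numeric(doc$r_sink)
  gnetwork(w_plus = matrix(as.numeric(doc$w_plus), n, n, byrow = TRUE),
           w_minus = matrix(as.numeric(doc$w_minus), n, n, byrow = TRUE),
           d = as.numeric(doc$d), r_sink = r_sink,
           field_label = as.character(doc$field_label))
}
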