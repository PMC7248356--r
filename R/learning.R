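#' Mean-squared-error cost
#'
#' The training objective: `sum_i 0.5 * (estimated_i - clean_i)^2`.
#'
#' @param estimated,clean equal-length numeric vectors.
#' @return Non-negative scalar.
#' @export
#' @examples
#' mse_cost(c(1, 2), c(0, 0))  # 2.5
mse_cost <- function(estimated, clean) {
  if (length(estimated) != length(clean))
    stop("length mismatch between estimated and clean vectors")
  sum(0.5 * (estimated - clean)^2)
}

# Structural edge mask: where weights can live. Defaults to the currently
# positive entries; training keeps the mask fixed so projection to zero does
# not delete an edge permanently from the update set.
default_mask <- function(net) {
  list(plus = net$w_plus > 0, minus = net$w_minus > 0)
}

#' Exact steady-state gradient of the MSE cost
#'
#' Differentiates the cost `sum 0.5 (q_out - target)^2` with respect to every
#' excitatory and inhibitory rate weight by implicit differentiation of the
#' steady-state fixed point: the adjoint of the linearised fixed-point map is
#' solved once per sample and chained through the cost, giving the gradient
#' for all weights at the price of one linear solve. The firing-rate
#' dependence on the outgoing row mass (`r_i = rowsum_i / (1 - d_i)`) is
#' included, so the gradient matches central finite differences applied to
#' "perturb weight, rebuild rates, re-solve".
#'
#' @param net a `gnetwork`.
#' @param arrivals an [external_arrivals()].
#' @param target desired excitation levels of the output neurons, in
#'   `[0, 1)`.
#' @param output_ids indices of the output neurons (default: neurons
#'   labelled `"OUT"`).
#' @param mask list of logical matrices `plus`/`minus` marking trainable
#'   edges (default: currently positive weights).
#' @param ss optional pre-computed steady state for `(net, arrivals)`.
#' @param check validate the network first (the training loop disables it).
#' @param ... passed to [solve_steady_state()].
#' @return List with gradient matrices `g_plus`, `g_minus` (zero off the
#'   mask), the steady state `ss` and the sample `loss`.
#' @export
gnet_gradient <- function(net, arrivals, target, output_ids = NULL,
                          mask = NULL, ss = NULL, check = TRUE, ...) {
  if (is.null(output_ids)) output_ids <- which(net$field_label == "OUT")
  stopifnot(length(output_ids) == length(target), length(output_ids) >= 1)
  if (is.null(mask)) mask <- default_mask(net)
  if (is.null(ss)) ss <- solve_steady_state(net, arrivals, check = check,
                                            ...)
  q <- ss$q
  n <- net$n_neurons
  r <- if (check) firing_rates(net) else firing_rates_raw(net)
  e <- numeric(n)
  e[output_ids] <- q[output_ids] - target
  core <- .gnet_gradient_core_cpp(net$w_plus, net$w_minus, r, net$d,
                                  arrivals$lambda_minus, q, e,
                                  is_sink(net))
  g_plus <- core$g_plus * mask$plus
  g_minus <- core$g_minus * mask$minus
  list(g_plus = g_plus, g_minus = g_minus, ss = ss,
       loss = mse_cost(q[output_ids], target))
}

#' Optimizer settings for G-network training
#'
#' @param method `"plain-gd"` or `"rmsprop"`.
#' @param learning_rate positive step size.
#' @param rmsprop_decay moving-average decay of squared gradients in (0, 1).
#' @param rmsprop_epsilon positive stabiliser inside the square root.
#' @param n_epochs number of passes over the data.
#' @param seed integer seed driving the per-epoch sample shuffling.
#' @return An object of class `optimizer_settings`.
#' @export
optimizer_settings <- function(method = c("rmsprop", "plain-gd"),
                               learning_rate = 0.01, rmsprop_decay = 0.9,
                               rmsprop_epsilon = 1e-8, n_epochs = 150,
                               seed = 0) {
  method <- match.arg(method)
  stopifnot(learning_rate >= 0, rmsprop_decay > 0, rmsprop_decay < 1,
            rmsprop_epsilon > 0, n_epochs >= 1)
  structure(list(method = method, learning_rate = learning_rate,
                 rmsprop_decay = rmsprop_decay,
                 rmsprop_epsilon = rmsprop_epsilon,
                 n_epochs = as.integer(n_epochs), seed = as.integer(seed)),
            class = "optimizer_settings")
}

#' Train G-network weights by stochastic gradient descent
#'
#' Per-sample updates in a freshly shuffled order each epoch (driven by the
#' settings seed), using the exact implicit-differentiation gradients of
#' [gnet_gradient()]. After every update the weights are projected onto the
#' non-negative orthant (they are Poisson rates). Only structurally present
#' edges (positive weights at entry) are updated. The steady-state solver is
#' warm-started from the previous sample's solution.
#'
#' The product-form regime additionally requires each neuron's service rate
#' to exceed its excitatory load. The projection therefore enforces a floor
#' on every trainable row's total outgoing rate mass of
#' `1.1 * max_samples(Lambda_i)` (never below a small constant that keeps
#' rows alive), which provably keeps the input neurons — whose load is purely
#' exogenous — inside the regime. Interior neurons are handled reactively:
#' if a steady-state solve saturates after an update, the saturated rows'
#' masses are scaled up until the solve succeeds again, so the optimizer is
#' only constrained where the regime actually requires it.
#'
#' @param net a `gnetwork`.
#' @param samples list of samples, each a list with elements `arrivals` (an
#'   `external_arrivals`) and `target` (desired output excitation levels in
#'   `[0, 1)`).
#' @param settings an [optimizer_settings()].
#' @param output_ids indices of output neurons (default: label `"OUT"`).
#' @param solver_tol steady-state tolerance used during training.
#' @param val_samples optional held-out samples; when given, the returned
#'   network is the epoch snapshot with the lowest validation loss (the
#'   usual guard against overfitting the per-environment structure).
#' @return List with the trained `net`, `loss` (per-epoch mean training
#'   loss), and — when validating — `val_loss` and `best_epoch`.
#' @export
train_gnetwork <- function(net, samples, settings,
                           output_ids = NULL, solver_tol = 1e-9,
                           val_samples = NULL) {
  stopifnot(inherits(settings, "optimizer_settings"), length(samples) >= 1)
  validate_gnetwork(net)
  if (is.null(output_ids)) output_ids <- which(net$field_label == "OUT")
  mask <- default_mask(net)
  slot_count <- rowSums(mask$plus | mask$minus)
  has_row <- rowSums(mask$plus) + rowSums(mask$minus) > 0
  drive <- vapply(samples, function(s) s$arrivals$Lambda,
                  numeric(net$n_neurons))
  drive <- if (is.matrix(drive)) apply(drive, 1, max) else drive
  v_plus <- matrix(0, net$n_neurons, net$n_neurons)
  v_minus <- v_plus
  loss_epoch <- numeric(settings$n_epochs)
  val_loss <- numeric(settings$n_epochs)
  best_val <- Inf
  best_net <- net
  best_epoch <- 0L
  q_warm <- NULL
  lr <- settings$learning_rate
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(settings$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (epoch in seq_len(settings$n_epochs)) {
    ord <- sample.int(length(samples))
    losses <- numeric(length(samples))
    for (k in seq_along(ord)) {
      s <- samples[[ord[k]]]
      g <- NULL
      for (rescue in 0:20) {
        g <- tryCatch(
          gnet_gradient(net, s$arrivals, s$target, output_ids = output_ids,
                        mask = mask, tol = solver_tol, q_init = q_warm,
                        check = FALSE),
          error = function(e) e)
        if (!inherits(g, "error")) break
        if (!inherits(g, "gnet_saturation")) stop(g)
        # scale up the saturated rows' service mass and retry
        sat <- g$neurons
        if (!length(sat)) stop(g)
        for (i in sat) {
          if (has_row[i]) {
            # raise the departure probability: this inflates the service
            # rate r = mass/(1-d) without injecting extra downstream
            # excitation (scaling the row itself can cascade saturation)
            net$d[i] <- 1 - (1 - net$d[i]) / 1.5
            if (sum(net$w_plus[i, ]) + sum(net$w_minus[i, ]) == 0) {
              net$w_plus[i, ] <- (0.1 / slot_count[i]) * mask$plus[i, ]
              net$w_minus[i, ] <- (0.1 / slot_count[i]) * mask$minus[i, ]
            }
          } else {              # fixed-rate sink: damp its excitatory load
            net$w_plus[, i] <- net$w_plus[, i] / 1.5
          }
        }
        q_warm <- NULL
      }
      if (inherits(g, "error")) stop(g)
      q_warm <- g$ss$q
      losses[k] <- g$loss
      if (settings$method == "rmsprop") {
        v_plus <- settings$rmsprop_decay * v_plus +
          (1 - settings$rmsprop_decay) * g$g_plus^2
        v_minus <- settings$rmsprop_decay * v_minus +
          (1 - settings$rmsprop_decay) * g$g_minus^2
        step_p <- g$g_plus / sqrt(v_plus + settings$rmsprop_epsilon)
        step_m <- g$g_minus / sqrt(v_minus + settings$rmsprop_epsilon)
      } else {
        step_p <- g$g_plus
        step_m <- g$g_minus
      }
      net$w_plus <- pmax(net$w_plus - lr * step_p, 0)
      net$w_minus <- pmax(net$w_minus - lr * step_m, 0)
      # off-mask entries started at zero and receive zero steps, so the
      # projection above keeps the structure without explicit re-masking
      row_floor <- has_row * pmax(0.05, 1.1 * drive)
      mass <- rowSums(net$w_plus) + rowSums(net$w_minus)
      low <- has_row & mass < row_floor
      if (any(low)) {
        dead <- which(low & mass == 0)
        if (length(dead)) {  # revive a fully zeroed row uniformly on its mask
          net$w_plus[dead, ] <- (row_floor[dead] / slot_count[dead]) *
            mask$plus[dead, , drop = FALSE]
          net$w_minus[dead, ] <- (row_floor[dead] / slot_count[dead]) *
            mask$minus[dead, , drop = FALSE]
          low[dead] <- FALSE
        }
        if (any(low)) {
          scl <- rep(1, length(mass))
          scl[low] <- row_floor[low] / mass[low]
          net$w_plus <- net$w_plus * scl
          net$w_minus <- net$w_minus * scl
        }
      }
    }
    loss_epoch[epoch] <- mean(losses)
    if (!is.finite(loss_epoch[epoch]))
      stop("training diverged (non-finite loss) at epoch ", epoch)
    if (!is.null(val_samples)) {
      val_loss[epoch] <- evaluate_mse(net, val_samples, output_ids)
      if (val_loss[epoch] < best_val) {
        best_val <- val_loss[epoch]
        best_net <- net
        best_epoch <- epoch
      }
    }
  }
  if (is.null(val_samples)) return(list(net = net, loss = loss_epoch))
  list(net = best_net, loss = loss_epoch, val_loss = val_loss,
       best_epoch = best_epoch)
}

#' Predicted outputs of a G-network for a list of samples
#'
#' Inputs that push the network out of the product-form regime are clipped
#' (an unstable neuron's activation fraction tends to one) rather than
#' raising an error, so held-out evaluation is always defined.
#'
#' @param net a `gnetwork`.
#' @param samples as in [train_gnetwork()].
#' @param output_ids output neuron indices (default: label `"OUT"`).
#' @return Matrix of output excitation probabilities, one row per sample.
#' @export
predict_gnetwork <- function(net, samples, output_ids = NULL) {
  if (is.null(output_ids)) output_ids <- which(net$field_label == "OUT")
  q_warm <- NULL
  out <- matrix(NA_real_, length(samples), length(output_ids))
  for (k in seq_along(samples)) {
    ss <- solve_steady_state(net, samples[[k]]$arrivals, q_init = q_warm,
                             on_saturation = "clip")
    q_warm <- ss$q
    out[k, ] <- ss$q[output_ids]
  }
  out
}

#' Mean per-sample MSE of a G-network on labelled samples
#'
#' @inheritParams predict_gnetwork
#' @return Mean of the per-sample [mse_cost()] values.
#' @export
evaluate_mse <- function(net, samples, output_ids = NULL) {
  if (is.null(output_ids)) output_ids <- which(net$field_label == "OUT")
  pred <- predict_gnetwork(net, samples, output_ids)
  mean(vapply(seq_along(samples), function(k)
    mse_cost(pred[k, ], samples[[k]]$target), numeric(1)))
}
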