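#' Configuration of a contextually adaptive neural network (CANN)
#'
#' A CANN is a G-network whose neurons are organised into parallel processing
#' streams of layered contextually adaptive neurons (CANs), fed by three
#' labelled input fields: the driving receptive field (RF), the modulatory
#' local contextual field (LCF) and the universal contextual field (UCF)
#' encoding the outside environment. When UCF units are present they form a
#' broadcast stream of their own, so the number of CAN-carrying streams is
#' `n_streams - 1`; with the defaults (3 streams, 3 layers, 2 CANs per
#' stream-layer, 4 RF + 4 LCF + 8 UCF inputs, 1 output) the network has
#' 12 CANs and 29 neurons in total.
#'
#' @param n_streams total number of streams, counting the UCF broadcast
#'   stream when `n_ucf_units > 0`.
#' @param n_layers number of CAN layers per stream.
#' @param n_rf_inputs,n_lcf_inputs,n_ucf_units input-field sizes.
#' @param cans_per_stream_layer CANs in each (stream, layer) cell.
#' @param n_outputs number of output (sink) neurons.
#' @param lateral_rule only `"neighboring-streams-same-layer"`: every CAN
#'   connects to all CANs of adjacent streams in its own layer (for two CAN
#'   streams each is the other's neighbour; for three or more, neighbours
#'   are adjacent indices, non-circular).
#' @param ucf_rule only `"broadcast-to-all-cans"`: every UCF unit feeds every
#'   CAN in all streams and layers.
#' @param init_weight_scale scale of the uniform `(0, scale]` draws that set
#'   the initial weight proportions within each neuron's outgoing row.
#' @param can_row_mass total outgoing rate mass each CAN row is normalized
#'   to (events/unit time). Input rows are normalized to total mass 2, so an
#'   input neuron's excitation probability is bounded by `rho / 2` for any
#'   encoding rate scale `rho <= 1`; see the vignette for the stability
#'   argument behind both masses.
#' @param r_sink_output explicit firing rate of the output sink neuron(s).
#' @param seed integer seed for the weight draws.
#' @return An object of class `cann_config`.
#' @export
cann_config <- function(n_streams = 3, n_layers = 3, n_rf_inputs = 4,
                        n_lcf_inputs = 4, n_ucf_units = 8,
                        cans_per_stream_layer = 2, n_outputs = 1,
                        lateral_rule = "neighboring-streams-same-layer",
                        ucf_rule = "broadcast-to-all-cans",
                        init_weight_scale = 0.1, can_row_mass = 6,
                        r_sink_output = 1, seed = 0) {
  cfg <- structure(
    list(n_streams = as.integer(n_streams), n_layers = as.integer(n_layers),
         n_rf_inputs = as.integer(n_rf_inputs),
         n_lcf_inputs = as.integer(n_lcf_inputs),
         n_ucf_units = as.integer(n_ucf_units),
         cans_per_stream_layer = as.integer(cans_per_stream_layer),
         n_outputs = as.integer(n_outputs),
         lateral_rule = match.arg(lateral_rule,
                                  "neighboring-streams-same-layer"),
         ucf_rule = match.arg(ucf_rule, "broadcast-to-all-cans"),
         init_weight_scale = as.numeric(init_weight_scale),
         can_row_mass = as.numeric(can_row_mass),
         r_sink_output = as.numeric(r_sink_output),
         seed = as.integer(seed)),
    class = "cann_config")
  with(cfg, {
    stopifnot(n_streams >= 1, n_layers >= 1, cans_per_stream_layer >= 1,
              n_outputs >= 1, n_rf_inputs >= 0, n_lcf_inputs >= 0,
              n_ucf_units >= 0, init_weight_scale > 0, can_row_mass > 0,
              r_sink_output > 0)
  })
  cfg
}

#' Number of CAN-carrying streams in a configuration
#'
#' The UCF broadcast stream (present when `n_ucf_units > 0`) carries no CANs.
#' @param config a `cann_config`.
#' @return Integer count.
#' @export
can_streams <- function(config) {
  s <- config$n_streams - as.integer(config$n_ucf_units > 0)
  if (s < 1)
    stop("invalid topology: no CAN-carrying streams")
  s
}

#' Read / write a CANN configuration file
#'
#' YAML (or JSON, which is a YAML subset) with one key per [cann_config()]
#' field; missing keys fall back to the defaults. A packaged default file
#' reproducing the 29-neuron reference network is at
#' `system.file("extdata", "cann_default.yaml", package = "cannets")`.
#'
#' @param path file path.
#' @param config a `cann_config` (for writing).
#' @return A `cann_config` / `path` invisibly.
#' @export
read_cann_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(cann_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(cann_config, vals)
}

#' @rdname read_cann_config
#' @export
write_cann_config <- function(config, path) {
  stopifnot(inherits(config, "cann_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Expand a CANN configuration into a G-network
#'
#' Builds the full weighted network: RF and LCF input neurons feed the
#' first-layer CANs of their streams (stream 1 and stream 2 respectively),
#' consecutive CAN layers are fully connected within a stream, every CAN has
#' lateral excitatory and inhibitory connections to all CANs of neighbouring
#' streams in its own layer, UCF units broadcast to every CAN, and last-layer
#' CANs feed the output neuron(s). Every structural connection — including
#' the input fields, whose filtering role is enforced by positive and
#' negative synaptic weights — carries an independent excitatory and
#' inhibitory learnable weight. Inhibitory input weights are what give the
#' UCF its divisive gain control over the processing streams.
#'
#' Initial weights are drawn uniformly from `(0, init_weight_scale]` with
#' the configuration seed and then row-normalized: each input neuron's
#' outgoing row to total rate 2 and each CAN's row to `can_row_mass`. The
#' draws set the proportions, the normalization keeps the network inside the
#' product-form regime for encoded inputs (see the vignette).
#'
#' @param config a [cann_config()].
#' @return An object of class `cann`: list with `net` (a `gnetwork`),
#'   `layout` (data.frame: neuron, field, stream, layer) and `config`.
#' @export
#' @examples
#' cann <- build_cann(cann_config())
#' cann$net$n_neurons  # 29
build_cann <- function(config) {
  stopifnot(inherits(config, "cann_config"))
  S <- can_streams(config)
  L <- config$n_layers
  C <- config$cans_per_stream_layer
  n_can <- S * L * C
  if (n_can < 1) stop("invalid topology: configuration has no CANs")

  field <- c(rep("RF", config$n_rf_inputs), rep("LCF", config$n_lcf_inputs),
             rep("UCF", config$n_ucf_units), rep("CAN", n_can),
             rep("OUT", config$n_outputs))
  n <- length(field)
  stream <- rep(NA_integer_, n)
  layer <- rep(NA_integer_, n)
  idx_rf <- which(field == "RF")
  idx_lcf <- which(field == "LCF")
  idx_ucf <- which(field == "UCF")
  idx_can <- which(field == "CAN")
  idx_out <- which(field == "OUT")

  # CANs ordered by (stream, layer, unit)
  can_grid <- expand.grid(unit = seq_len(C), layer = seq_len(L),
                          stream = seq_len(S))
  stream[idx_can] <- can_grid$stream
  layer[idx_can] <- can_grid$layer
  lcf_stream <- min(2L, S)
  stream[idx_rf] <- 1L
  stream[idx_lcf] <- lcf_stream
  if (config$n_ucf_units > 0) stream[idx_ucf] <- S + 1L
  layer[c(idx_rf, idx_lcf, idx_ucf)] <- 0L
  layer[idx_out] <- L + 1L

  can_at <- function(s, l) idx_can[can_grid$stream == s & can_grid$layer == l]

  edges_p <- matrix(FALSE, n, n)  # excitatory slots
  edges_m <- matrix(FALSE, n, n)  # inhibitory slots
  edges_p[idx_rf, can_at(1L, 1L)] <- TRUE
  edges_m[idx_rf, can_at(1L, 1L)] <- TRUE
  if (length(idx_lcf)) {
    edges_p[idx_lcf, can_at(lcf_stream, 1L)] <- TRUE
    edges_m[idx_lcf, can_at(lcf_stream, 1L)] <- TRUE
  }
  if (length(idx_ucf)) {
    edges_p[idx_ucf, idx_can] <- TRUE
    edges_m[idx_ucf, idx_can] <- TRUE
  }
  for (s in seq_len(S)) {
    if (L > 1) for (l in seq_len(L - 1)) {
      edges_p[can_at(s, l), can_at(s, l + 1L)] <- TRUE
      edges_m[can_at(s, l), can_at(s, l + 1L)] <- TRUE
    }
    for (s2 in seq_len(S)) {
      if (abs(s2 - s) == 1L) for (l in seq_len(L)) {
        edges_p[can_at(s, l), can_at(s2, l)] <- TRUE
        edges_m[can_at(s, l), can_at(s2, l)] <- TRUE
      }
    }
    edges_p[can_at(s, L), idx_out] <- TRUE
    edges_m[can_at(s, L), idx_out] <- TRUE
  }
  diag(edges_p) <- FALSE
  diag(edges_m) <- FALSE

  old <- get0(".Random.seed", envir = globalenv())
  set.seed(config$seed)
  w_plus <- matrix(0, n, n)
  w_minus <- matrix(0, n, n)
  # uniform (0, scale]: proportions within each row before normalization
  w_plus[edges_p] <- stats::runif(sum(edges_p)) * config$init_weight_scale
  w_minus[edges_m] <- stats::runif(sum(edges_m)) * config$init_weight_scale
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  row_mass <- rowSums(w_plus) + rowSums(w_minus)
  target_mass <- ifelse(field %in% c("RF", "LCF", "UCF"), 2,
                        ifelse(field == "CAN", config$can_row_mass, 0))
  scale <- ifelse(row_mass > 0, target_mass / row_mass, 0)
  w_plus <- w_plus * scale
  w_minus <- w_minus * scale

  if (any(colSums(w_plus[, idx_can, drop = FALSE]) +
            colSums(w_minus[, idx_can, drop = FALSE]) == 0))
    stop("invalid topology: a CAN has no incoming connection")
  if (any(colSums(w_plus[, idx_out, drop = FALSE]) == 0))
    stop("invalid topology: output neuron unreachable")

  r_sink <- rep(NA_real_, n)
  r_sink[idx_out] <- config$r_sink_output
  net <- gnetwork(w_plus, w_minus, d = 0, r_sink = r_sink,
                  field_label = field)
  layout <- data.frame(neuron = seq_len(n), field = field,
                       stream = stream, layer = layer)
  structure(list(net = net, layout = layout, config = config),
            class = "cann")
}

#' @export
print.cann <- function(x, ...) {
  cfg <- x$config
  cat("CANN:", can_streams(cfg), "CAN stream(s) x", cfg$n_layers,
      "layer(s) x", cfg$cans_per_stream_layer, "CAN(s);",
      cfg$n_rf_inputs, "RF +", cfg$n_lcf_inputs, "LCF +",
      cfg$n_ucf_units, "UCF inputs;", cfg$n_outputs, "output(s) =>",
      x$net$n_neurons, "neurons\n")
  invisible(x)
}

#' Write the CANN layout as CSV
#'
#' @param cann a `cann` object.
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_cann_layout <- function(cann, path) {
  utils::write.csv(cann$layout, path, row.names = FALSE)
  invisible(path)
}

#' Min-max input encoding into Poisson arrival-rate pairs
#'
#' Each feature value is min-max scaled into `[0, 1]` (clipping outside the
#' bounds) and mapped to a pair of external Poisson rates: excitatory
#' `Lambda = s * rho` and inhibitory `lambda = (1 - s) * rho`, so the total
#' exogenous drive per input neuron is the constant rate scale `rho` and the
#' balance encodes the value.
#'
#' @param rate_scale positive rate scale `rho` (events/unit time).
#' @param min,max per-feature normalization bounds (recycled).
#' @return An object of class `input_encoding`.
#' @export
input_encoding <- function(rate_scale = 1, min = 0, max = 1) {
  stopifnot(rate_scale > 0, all(is.finite(min)), all(is.finite(max)),
            all(min < max))
  structure(list(rate_scale = rate_scale, min = min, max = max),
            class = "input_encoding")
}

#' Encode a feature vector as external arrival-rate pairs
#'
#' @param x numeric feature vector, one value per input neuron.
#' @param enc an [input_encoding()] whose bounds recycle to `length(x)`.
#' @return A matrix with columns `Lambda` and `lambda`, one row per feature.
#' @export
#' @examples
#' encode_features(5, input_encoding(rate_scale = 2, min = 0, max = 10))
encode_features <- function(x, enc) {
  stopifnot(inherits(enc, "input_encoding"))
  if (any(!is.finite(x))) stop("encoding error: non-finite feature values")
  lo <- rep_len(enc$min, length(x))
  hi <- rep_len(enc$max, length(x))
  s <- pmin(pmax((x - lo) / (hi - lo), 0), 1)
  cbind(Lambda = s * enc$rate_scale, lambda = (1 - s) * enc$rate_scale)
}

#' Average a feature vector into contiguous blocks
#'
#' Maps a feature vector of arbitrary dimension onto a fixed number of input
#' neurons by averaging contiguous blocks (the blocks differ by at most one
#' element in size).
#'
#' @param x numeric vector.
#' @param n_out number of output blocks.
#' @return Length-`n_out` numeric vector.
#' @export
block_average <- function(x, n_out) {
  stopifnot(n_out >= 1, length(x) >= 1)
  grp <- ceiling(seq_along(x) / (length(x) / n_out))
  grp <- pmin(grp, n_out)
  as.numeric(tapply(x, grp, mean))
}

#' Arrival rates for one multimodal sample
#'
#' Encodes RF features, LCF features and the binary UCF pattern of a single
#' sample into a full-length [external_arrivals()] object for a built CANN.
#' Feature vectors longer than the corresponding input field are
#' block-averaged down to it first. UCF bits are encoded directly
#' (bit 1: `Lambda = rho`, bit 0: `lambda = rho`).
#'
#' @param cann a [build_cann()] result.
#' @param rf,lcf numeric feature vectors (possibly longer than the fields).
#' @param ucf binary vector of length `n_ucf_units`.
#' @param rf_enc,lcf_enc [input_encoding()] objects with per-input-neuron
#'   bounds (after block averaging).
#' @param rate_scale rate scale for the UCF bits.
#' @return An `external_arrivals` object of length `n_neurons`.
#' @export
cann_arrivals <- function(cann, rf = NULL, lcf = NULL, ucf = NULL,
                          rf_enc = input_encoding(),
                          lcf_enc = input_encoding(), rate_scale = 1) {
  lay <- cann$layout
  n <- cann$net$n_neurons
  Lambda <- numeric(n)
  lambda <- numeric(n)
  fill <- function(ids, pairs) {
    Lambda[ids] <<- pairs[, "Lambda"]
    lambda[ids] <<- pairs[, "lambda"]
  }
  rf_ids <- which(lay$field == "RF")
  lcf_ids <- which(lay$field == "LCF")
  ucf_ids <- which(lay$field == "UCF")
  if (length(rf_ids) && !is.null(rf))
    fill(rf_ids, encode_features(block_average(rf, length(rf_ids)), rf_enc))
  if (length(lcf_ids) && !is.null(lcf))
    fill(lcf_ids,
         encode_features(block_average(lcf, length(lcf_ids)), lcf_enc))
  if (length(ucf_ids) && !is.null(ucf)) {
    bits <- rep_len(as.numeric(ucf), length(ucf_ids))
    fill(ucf_ids, cbind(Lambda = bits * rate_scale,
                        lambda = (1 - bits) * rate_scale))
  }
  external_arrivals(Lambda, lambda, n = n)
}
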