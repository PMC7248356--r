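block_matrix <- function(dim_in, n_out) {
  grp <- pmin(ceiling(seq_len(dim_in) / (dim_in / n_out)), n_out)
  B <- matrix(0, dim_in, n_out)
  B[cbind(seq_len(dim_in), grp)] <- 1
  sweep(B, 2, colSums(B), "/")
}

#' Fit a feature encoder for a CANN on (training) records
#'
#' Block-averages the RF and LCF feature blocks down to the network's input
#' fields and records per-input min/max normalization bounds from the given
#' records. The returned encoder is then applied unchanged to held-out data.
#'
#' @param cann a [build_cann()] result.
#' @param dataset a `synthetic_dataset` (typically the training split).
#' @param rate_scale encoding rate scale `rho`.
#' @return An object of class `cann_encoder`.
#' @export
fit_encoder <- function(cann, dataset, rate_scale = 1) {
  lay <- cann$layout
  enc <- list(rate_scale = rate_scale,
              n_rf = sum(lay$field == "RF"), n_lcf = sum(lay$field == "LCF"),
              n_ucf = sum(lay$field == "UCF"))
  if (enc$n_rf > 0) {
    rf <- feature_block(dataset, "rf")
    enc$rf_block <- block_matrix(ncol(rf), enc$n_rf)
    avg <- rf %*% enc$rf_block
    enc$rf_lo <- apply(avg, 2, min)
    enc$rf_hi <- apply(avg, 2, max)
  }
  if (enc$n_lcf > 0) {
    lcf <- feature_block(dataset, "lcf")
    enc$lcf_block <- block_matrix(ncol(lcf), enc$n_lcf)
    avg <- lcf %*% enc$lcf_block
    enc$lcf_lo <- apply(avg, 2, min)
    enc$lcf_hi <- apply(avg, 2, max)
  }
  structure(enc, class = "cann_encoder")
}

# Scaled (0..1) input values per record for one field; matrix n_rec x n_in.
scaled_inputs <- function(enc, dataset, field) {
  if (field == "rf") {
    avg <- feature_block(dataset, "rf") %*% enc$rf_block
    lo <- enc$rf_lo; hi <- enc$rf_hi
  } else {
    avg <- feature_block(dataset, "lcf") %*% enc$lcf_block
    lo <- enc$lcf_lo; hi <- enc$lcf_hi
  }
  s <- sweep(sweep(avg, 2, lo), 2, pmax(hi - lo, .Machine$double.eps), "/")
  pmin(pmax(s, 0), 1)
}

#' Encode dataset records as training samples for a CANN
#'
#' @param cann a [build_cann()] result.
#' @param dataset a `synthetic_dataset`.
#' @param enc a [fit_encoder()] result.
#' @param lcf_shift additive perturbation applied to the scaled LCF inputs
#'   (clipped back into `[0, 1]`); used by the modulation analysis.
#' @return List of samples, each with `arrivals` and `target`.
#' @export
cann_samples <- function(cann, dataset, enc, lcf_shift = 0) {
  lay <- cann$layout
  n <- cann$net$n_neurons
  n_rec <- nrow(dataset)
  rho <- enc$rate_scale
  S <- matrix(0, n_rec, n)   # scaled drive per neuron
  if (enc$n_rf > 0)
    S[, lay$field == "RF"] <- scaled_inputs(enc, dataset, "rf")
  if (enc$n_lcf > 0)
    S[, lay$field == "LCF"] <- pmin(pmax(
      scaled_inputs(enc, dataset, "lcf") + lcf_shift, 0), 1)
  if (enc$n_ucf > 0)
    S[, lay$field == "UCF"] <- as.matrix(
      feature_block(dataset, "ucf"))[, seq_len(enc$n_ucf), drop = FALSE]
  is_input <- lay$field %in% c("RF", "LCF", "UCF")
  lapply(seq_len(n_rec), function(k) {
    Lambda <- ifelse(is_input, S[k, ] * rho, 0)
    lambda <- ifelse(is_input, (1 - S[k, ]) * rho, 0)
    list(arrivals = external_arrivals(Lambda, lambda, n = n),
         target = dataset$target[k])
  })
}

#' Train a CANN on a synthetic dataset
#'
#' Fits the feature encoder on the supplied records, encodes them and trains
#' the network weights with [train_gnetwork()]. When validation records are
#' supplied the returned network is the epoch snapshot with the lowest
#' validation MSE.
#'
#' @param cann a [build_cann()] result.
#' @param dataset training records.
#' @param settings an [optimizer_settings()].
#' @param rate_scale encoding rate scale.
#' @param val_dataset optional held-out records for epoch selection.
#' @return An object of class `trained_cann`: `cann`, trained `net`,
#'   `encoder`, `settings`, the per-epoch `loss` trajectory and (when
#'   validating) `val_loss` and `best_epoch`.
#' @export
train_cann <- function(cann, dataset, settings = optimizer_settings(),
                       rate_scale = 1, val_dataset = NULL) {
  enc <- fit_encoder(cann, dataset, rate_scale)
  samples <- cann_samples(cann, dataset, enc)
  val_samples <- if (!is.null(val_dataset))
    cann_samples(cann, val_dataset, enc)
  fit <- train_gnetwork(cann$net, samples, settings,
                        val_samples = val_samples)
  structure(list(cann = cann, net = fit$net, encoder = enc,
                 settings = settings, loss = fit$loss,
                 val_loss = fit$val_loss, best_epoch = fit$best_epoch),
            class = "trained_cann")
}

#' Predicted outputs of a trained CANN on dataset records
#'
#' @param model a [train_cann()] result.
#' @param dataset records to predict.
#' @param lcf_shift perturbation of the scaled LCF inputs (see
#'   [cann_samples()]).
#' @return Matrix of output excitation probabilities (rows = records).
#' @export
predict_cann <- function(model, dataset, lcf_shift = 0) {
  samples <- cann_samples(model$cann, dataset, model$encoder, lcf_shift)
  predict_gnetwork(model$net, samples)
}

ablation_variants <- c("RF-only", "RF+LCF", "RF+LCF+UCF")

variant_config <- function(base, variant) {
  s_can <- can_streams(base)
  fields <- unclass(base)
  switch(variant,
    "RF-only" = do.call(cann_config, utils::modifyList(
      fields, list(n_streams = s_can, n_lcf_inputs = 0L, n_ucf_units = 0L))),
    "RF+LCF" = do.call(cann_config, utils::modifyList(
      fields, list(n_streams = s_can, n_ucf_units = 0L))),
    "RF+LCF+UCF" = do.call(cann_config, fields),
    stop("unknown variant ", variant))
}

default_experiment_config <- function(config = list()) {
  utils::modifyList(
    list(params = dataset_params(), cann = cann_config(),
         settings = optimizer_settings(), train_frac = 0.8,
         rate_scale = 1),
    config)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

split_dataset <- function(dataset, train_frac, seed, val_frac = 0) {
  seqs <- unique(dataset$seq)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed + 10000L)
  seqs <- sample(seqs)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  n_train <- max(1, floor(train_frac * length(seqs)))
  test <- dataset[dataset$seq %in% seqs[-seq_len(n_train)], ]
  train_seqs <- seqs[seq_len(n_train)]
  if (val_frac > 0) {
    n_val <- max(1, floor(val_frac * length(train_seqs)))
    val_seqs <- train_seqs[seq_len(n_val)]
    train_seqs <- setdiff(train_seqs, val_seqs)
    return(list(train = dataset[dataset$seq %in% train_seqs, ],
                val = dataset[dataset$seq %in% val_seqs, ], test = test))
  }
  list(train = dataset[dataset$seq %in% train_seqs, ], test = test)
}

#' Ablation of the input fields: RF-only vs RF+LCF vs RF+LCF+UCF
#'
#' For each seed a fresh synthetic dataset is generated and split by
#' sequence into train/validation/test; for each variant the CANN is built
#' with the unused input fields removed (the CAN fabric is unchanged),
#' trained on the training split with validation-based epoch selection, and
#' scored on the held-out test split. A training failure is recorded as a
#' failed seed (NA), not silently dropped.
#'
#' @param config list overriding any of `params` ([dataset_params()]),
#'   `cann` ([cann_config()]), `settings` ([optimizer_settings()]),
#'   `train_frac`, `rate_scale`.
#' @param seeds integer vector of at least 3 seeds.
#' @return An object of class `ablation_result`: `results` (data.frame of
#'   variant/seed/MSE), `medians`, `seeds`, `config_hash`, and `model` (the
#'   trained full-variant model of the first seed, for reuse in
#'   [modulation_analysis()]) with its `test` split.
#' @export
run_ablation <- function(config = list(), seeds = 0:4) {
  stopifnot(length(seeds) >= 3)
  cfg <- default_experiment_config(config)
  rows <- list()
  first_model <- NULL
  first_test <- NULL
  for (seed in seeds) {
    ds <- generate_dataset(cfg$params, seed = seed)
    sp <- split_dataset(ds, cfg$train_frac, seed, val_frac = 0.2)
    for (variant in ablation_variants) {
      vcfg <- variant_config(cfg$cann, variant)
      vcfg$seed <- as.integer(seed)
      cann <- build_cann(vcfg)
      settings <- cfg$settings
      settings$seed <- as.integer(seed)
      mse <- tryCatch({
        model <- train_cann(cann, sp$train, settings, cfg$rate_scale,
                            val_dataset = sp$val)
        if (variant == "RF+LCF+UCF" && is.null(first_model)) {
          first_model <- model
          first_test <- sp$test
        }
        test_samples <- cann_samples(cann, sp$test, model$encoder)
        evaluate_mse(model$net, test_samples)
      }, error = function(e) {
        warning("seed ", seed, " variant ", variant, " failed: ",
                conditionMessage(e))
        NA_real_
      })
      rows[[length(rows) + 1]] <- data.frame(
        variant = variant, seed = seed, mse = mse)
    }
  }
  results <- do.call(rbind, rows)
  medians <- vapply(ablation_variants, function(v)
    stats::median(results$mse[results$variant == v], na.rm = TRUE),
    numeric(1))
  structure(list(results = results, medians = medians, seeds = seeds,
                 config_hash = config_hash(cfg), model = first_model,
                 test = first_test),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("Input-field ablation over", length(x$seeds), "seeds (median test MSE)\n")
  print(round(x$medians, 5))
  invisible(x)
}

#' Contextual-modulation analysis of a trained CANN
#'
#' Quantifies the influence of the local contextual field (LCF) on the
#' output in each environment, two ways: (a) the conditional mutual
#' information `I(Y; Z | X, U)` estimated from a binned joint histogram of
#' mean scaled RF input (X), mean scaled LCF input (Z), the environment (U)
#' and the model output (Y); and (b) a perturbation sensitivity, the mean
#' absolute output change per unit shift of the scaled LCF inputs
#' (`+- delta`). The rank correlation of each measure against the
#' environment's mean SNR summarises whether contextual modulation fades as
#' the acoustic environment gets cleaner.
#'
#' @param model a [train_cann()] result (trained with all three fields).
#' @param dataset records covering all five environments.
#' @param delta perturbation of the scaled LCF inputs.
#' @param n_bins bins per axis for the pmf estimate.
#' @return An object of class `modulation_report`: `by_env` (data.frame:
#'   env, mean_snr, n, lcf_sensitivity, cmi_bits), `spearman_sensitivity`,
#'   `spearman_cmi`.
#' @export
modulation_analysis <- function(model, dataset, delta = 0.05, n_bins = 4) {
  stopifnot(inherits(model, "trained_cann"))
  if (model$encoder$n_lcf == 0)
    stop("model was not trained with an LCF input field")
  specs <- environment_specs()
  missing <- setdiff(specs$name, unique(dataset$env))
  if (length(missing))
    stop("missing environment coverage: ", paste(missing, collapse = ", "))
  rows <- lapply(specs$name, function(e) {
    d <- dataset[dataset$env == e, ]
    y <- drop(predict_cann(model, d))
    y_plus <- drop(predict_cann(model, d, lcf_shift = delta))
    y_minus <- drop(predict_cann(model, d, lcf_shift = -delta))
    sens <- mean(abs(y_plus - y_minus)) / (2 * delta)
    x_in <- rowMeans(scaled_inputs(model$encoder, d, "rf"))
    z_in <- rowMeans(scaled_inputs(model$encoder, d, "lcf"))
    u_in <- rowMeans(feature_block(d, "ucf"))
    pmf <- estimate_pmf(data.frame(X = x_in, Z = z_in, U = u_in, Y = y),
                        n_bins = n_bins)
    cmi <- conditional_mutual_information(pmf, "Z", "Y", c("X", "U"))
    data.frame(env = e, mean_snr = mean(d$snr_db), n = nrow(d),
               lcf_sensitivity = sens, cmi_bits = cmi)
  })
  by_env <- do.call(rbind, rows)
  spearman <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = "spearman")
  }
  structure(list(
    by_env = by_env,
    spearman_sensitivity = spearman(by_env$mean_snr, by_env$lcf_sensitivity),
    spearman_cmi = spearman(by_env$mean_snr, by_env$cmi_bits),
    delta = delta), class = "modulation_report")
}

#' @export
print.modulation_report <- function(x, ...) {
  cat("Contextual modulation by environment\n")
  print(x$by_env, row.names = FALSE)
  cat(sprintf("Spearman(SNR, sensitivity) = %.3f; Spearman(SNR, CMI) = %.3f\n",
              x$spearman_sensitivity, x$spearman_cmi))
  invisible(x)
}
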