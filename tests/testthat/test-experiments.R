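tiny_exp_config <- function() {
  list(params = dataset_params(n_sequences = 8, seq_len = 6),
       settings = optimizer_settings(n_epochs = 3, seed = 0))
}

test_that("the ablation harness produces the three variants per seed", {
  ab <- run_ablation(tiny_exp_config(), seeds = 0:2)
  expect_s3_class(ab, "ablation_result")
  expect_setequal(unique(ab$results$variant),
                  c("RF-only", "RF+LCF", "RF+LCF+UCF"))
  expect_equal(nrow(ab$results), 9)
  expect_true(all(ab$results$mse >= 0, na.rm = TRUE))
  expect_equal(length(ab$medians), 3)
  expect_true(nzchar(ab$config_hash))
  expect_s3_class(ab$model, "trained_cann")
})

test_that("repeated ablation runs reproduce the recorded MSEs exactly", {
  a <- run_ablation(tiny_exp_config(), seeds = 0:2)
  b <- run_ablation(tiny_exp_config(), seeds = 0:2)
  expect_identical(a$results$mse, b$results$mse)
  expect_identical(a$config_hash, b$config_hash)
})

test_that("an uninformative LCF stream cannot beat the RF-only model", {
  # drown the visual stream in noise: its correlation with the clean
  # features is negligible, so RF-only and RF+LCF should be statistically
  # indistinguishable (overlapping seed ranges)
  cfg <- list(params = dataset_params(n_sequences = 10, seq_len = 8,
                                      lcf_noise_sd = 100),
              settings = optimizer_settings(n_epochs = 6, seed = 0))
  ab <- run_ablation(cfg, seeds = 0:3)
  rf <- ab$results$mse[ab$results$variant == "RF-only"]
  rflcf <- ab$results$mse[ab$results$variant == "RF+LCF"]
  expect_true(min(rf) <= max(rflcf) && min(rflcf) <= max(rf))
})

# A hand-built teacher whose LCF path is gated by the UCF units that are
# active only in the quiet bands, evaluated on records that are identical
# across environments except for the UCF pattern.
gated_teacher <- function() {
  # neurons: RF(1), LCF(2), UCF(3..10), gate CAN(11), OUT(12), dump(13)
  n <- 13
  wp <- matrix(0, n, n)
  wm <- matrix(0, n, n)
  wp[1, 12] <- 0.4; wm[1, 12] <- 1.6    # weak direct RF path (row mass 2)
  wp[2, 11] <- 1.4; wm[2, 11] <- 0.6    # LCF drives the gate CAN
  # the records below set the first two UCF bits exactly in the three
  # quietest bands: those units throttle the gate with their whole row mass
  wm[3, 11] <- 2; wm[4, 11] <- 2
  for (u in 5:10) wm[u, 13] <- 2        # inert rows drain into the dump
  wp[11, 12] <- 1                          # gate to output
  field <- c("RF", "LCF", rep("UCF", 8), "CAN", "OUT", "CAN")
  net <- gnetwork(wp, wm, d = 0, r_sink = c(rep(NA, n - 2), 1, 1),
                  field_label = field)
  layout <- data.frame(neuron = 1:n, field = field,
                       stream = c(1, 1, rep(2, 8), 1, NA, NA),
                       layer = c(0, 0, rep(0, 8), 1, 2, 2))
  cfg <- cann_config(n_streams = 2, n_layers = 1, n_rf_inputs = 1,
                     n_lcf_inputs = 1, n_ucf_units = 8,
                     cans_per_stream_layer = 1)
  structure(list(net = net, layout = layout, config = cfg), class = "cann")
}

replicated_env_records <- function(n_per_env = 12) {
  specs <- environment_specs()
  set.seed(31)
  base <- data.frame(rf_1 = runif(n_per_env), lcf_1 = runif(n_per_env),
                     target = runif(n_per_env, 0.2, 0.6))
  # constructed patterns: bits 1-2 flag the three quietest bands, bits 3-7
  # one-hot the environment index (the teacher above gates on bits 1-2)
  do.call(rbind, lapply(seq_len(nrow(specs)), function(i) {
    d <- base
    d$env <- specs$name[i]
    d$snr_db <- (specs$snr_lo[i] + specs$snr_hi[i]) / 2
    d$seq <- i
    quiet <- as.numeric(i >= 3)
    pat <- c(quiet, quiet, as.numeric(seq_len(5) == i), 0)
    pats <- matrix(pat, n_per_env, 8, byrow = TRUE)
    colnames(pats) <- paste0("ucf_", 1:8)
    cbind(d, pats)
  }))
}

test_that("a UCF-gated LCF path yields strongly negative SNR correlation", {
  cann <- gated_teacher()
  records <- replicated_env_records()
  enc <- fit_encoder(cann, records)
  model <- structure(list(cann = cann, net = cann$net, encoder = enc,
                          settings = NULL, loss = NULL),
                     class = "trained_cann")
  rep <- modulation_analysis(model, records)
  expect_lte(rep$spearman_sensitivity, -0.8)
  s <- rep$by_env
  noisy <- s$lcf_sensitivity[s$env == "restaurant"]
  quiet <- s$lcf_sensitivity[s$env == "home"]
  expect_lt(quiet, 0.5 * noisy)
})

test_that("a model with zero LCF weights shows no LCF influence", {
  cann <- gated_teacher()
  cann$net$w_plus[2, ] <- 0
  cann$net$w_minus[2, ] <- 0
  cann$net$r_sink[2] <- 2           # now a sink input: needs explicit rate
  records <- replicated_env_records(250)
  enc <- fit_encoder(cann, records)
  model <- structure(list(cann = cann, net = cann$net, encoder = enc,
                          settings = NULL, loss = NULL),
                     class = "trained_cann")
  rep <- modulation_analysis(model, records)
  expect_equal(rep$by_env$lcf_sensitivity, rep(0, 5), tolerance = 1e-12)
  expect_true(all(rep$by_env$cmi_bits < 0.05))
})

test_that("modulation analysis requires full environment coverage", {
  cann <- gated_teacher()
  records <- replicated_env_records(6)
  records <- records[records$env != "home", ]
  enc <- fit_encoder(cann, records)
  model <- structure(list(cann = cann, net = cann$net, encoder = enc,
                          settings = NULL, loss = NULL),
                     class = "trained_cann")
  expect_error(modulation_analysis(model, records), "coverage")
})
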