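test_that("SNR mixing scales noise power exactly", {
  set.seed(1)
  clean <- stats::rnorm(4000)
  noise <- stats::rnorm(4000)
  mixed0 <- mix_at_snr(clean, noise, 0)
  expect_equal(mean((mixed0 - clean)^2), mean(clean^2), tolerance = 1e-12)
  mixed6 <- mix_at_snr(clean, noise, 6)
  expect_equal(mean((mixed6 - clean)^2), mean(clean^2) / 10^0.6,
               tolerance = 1e-12)
  expect_equal(empirical_snr(clean, mixed6), 6, tolerance = 1e-9)
  # very high SNR approaches the clean signal
  mixed60 <- mix_at_snr(clean, noise, 60)
  expect_lt(mean((mixed60 - clean)^2) / mean(clean^2), 1e-3)
  expect_error(mix_at_snr(numeric(10), noise[1:10], 0), "zero-power")
  expect_error(mix_at_snr(clean[1:10], numeric(10), 0), "zero-power")
})

test_that("framing arithmetic matches the sampling geometry", {
  expect_equal(ncol(frame_signal(numeric(800), 50000, 16, 62.5)), 800)
  expect_equal(ncol(frame_signal(numeric(1000), 1000, 1000, 50)), 1000)
  f <- frame_signal(numeric(10000), 50000, 16, 62.5)
  expect_equal(nrow(f), 19)   # hop = 500 samples
  expect_equal(nrow(frame_signal(numeric(799), 50000, 16, 62.5)), 0)
  expect_error(frame_signal(numeric(100), 1000, 10, 1), "hop")
  # frames tile the signal with the expected offset
  sig <- seq_len(2000)
  fr <- frame_signal(sig, 1000, 100, 50)
  expect_equal(fr[2, 1], 51)
})

test_that("environment bands partition the SNR range with distinct codes", {
  specs <- environment_specs()
  expect_equal(nrow(specs), 5)
  expect_setequal(specs$name, c("cafe", "restaurant", "public transport",
                                "pedestrian area", "home"))
  expect_equal(specs$snr_lo[1], -12)
  expect_equal(specs$snr_hi[5], 12)
  expect_equal(specs$snr_lo[-1], specs$snr_hi[-5])   # exact partition
  pats <- as.matrix(specs[, paste0("u", 1:8)])
  for (a in 1:4) for (b in (a + 1):5)
    expect_gte(sum(pats[a, ] != pats[b, ]), 4)        # Hamming >= 4
})

test_that("SNR-to-environment lookup uses half-open bands", {
  expect_equal(env_for_snr(-12)$name, "restaurant")
  expect_equal(env_for_snr(-7.2)$name, "cafe")       # boundary goes right
  expect_equal(env_for_snr(0)$name, "public transport")
  expect_equal(env_for_snr(12)$name, "home")         # top band closed
  expect_error(env_for_snr(12.5), "out of range")
  expect_error(env_for_snr(-13), "out of range")
})

test_that("generated datasets honour their construction contracts", {
  params <- dataset_params(n_sequences = 12, seq_len = 10)
  ds <- generate_dataset(params, seed = 3)
  expect_equal(nrow(ds), 120)
  expect_true(all(ds$target >= 0 & ds$target < 1))

  # per-sequence empirical SNR equals the nominal one
  for (s in unique(ds$seq)) {
    d <- ds[ds$seq == s, ]
    snr <- empirical_snr(as.vector(feature_block(d, "clean")),
                         as.vector(feature_block(d, "rf")))
    expect_lt(abs(snr - d$snr_db[1]), 0.5)
    # UCF pattern is the deterministic codebook entry of the environment
    spec <- env_for_snr(d$snr_db[1])
    expect_equal(unname(feature_block(d, "ucf")[1, ]),
                 as.numeric(spec[paste0("u", 1:8)]))
    expect_equal(d$env[1], spec$name)
  }

  # determinism: same seed reproduces bit for bit, new seed redraws features
  ds2 <- generate_dataset(params, seed = 3)
  expect_identical(as.data.frame(ds), as.data.frame(ds2))
  ds3 <- generate_dataset(params, seed = 4)
  expect_false(identical(ds$clean_1, ds3$clean_1))
})

test_that("LCF tracks the clean stream and RF degrades with noise", {
  ds <- generate_dataset(dataset_params(n_sequences = 25, seq_len = 15),
                         seed = 9)
  lcf_map <- attr(ds, "lcf_map")
  proj <- feature_block(ds, "clean") %*% t(lcf_map)
  # the default visual-noise level sits between the clean and noisy
  # acoustic extremes, so the correlation is strong but not near-perfect
  expect_gt(stats::cor(as.vector(proj), as.vector(feature_block(ds, "lcf"))),
            0.7)
  # noiseless LCF is an exact linear image of clean
  ds0 <- generate_dataset(dataset_params(n_sequences = 4, seq_len = 10,
                                         lcf_noise_sd = 0), seed = 1)
  proj0 <- feature_block(ds0, "clean") %*% t(attr(ds0, "lcf_map"))
  expect_equal(unname(feature_block(ds0, "lcf")), unname(proj0),
               tolerance = 1e-12)
  # RF-clean correlation rises monotonically across the five bands
  cors <- vapply(environment_specs()$name, function(e) {
    d <- ds[ds$env == e, ]
    stats::cor(as.vector(feature_block(d, "clean")),
               as.vector(feature_block(d, "rf")))
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
})

test_that("dataset CSV round trip preserves records and parameters", {
  ds <- generate_dataset(dataset_params(n_sequences = 3, seq_len = 5),
                         seed = 8)
  path <- tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(back$target, ds$target, tolerance = 1e-12)
  expect_equal(attr(back, "params")$n_sequences, 3)
  expect_equal(attr(back, "seed"), 8)
  unlink(c(path, paste0(path, ".json")))
})

test_that("printed sentence bookkeeping adds up to the grand total", {
  s <- sentence_count_summary()
  expect_equal(unname(s$totals["total"]), 4734)
  expect_equal(sum(s$per_speaker$used_aligned), 4734)
  expect_equal(unname(s$totals["train"] + s$totals["validation"] +
                        s$totals["test"]), 4734)
  expect_equal(s$per_speaker$total, s$per_speaker$used_aligned)
})
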