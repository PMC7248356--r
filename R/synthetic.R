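#' Environment specifications for the synthetic multimodal task
#'
#' Five acoustic environments partition the SNR range `[-12, 12]` dB into
#' equal-width bands ordered by intuitive noisiness (restaurant noisiest,
#' home quietest). Each environment is identified by a fixed 8-bit binary
#' pattern (the universal contextual field code); the five codewords have
#' pairwise Hamming distance >= 4 and constant weight (four active bits
#' each), so the total exogenous drive the pattern injects into a network
#' is the same in every environment — only its shape differs.
#'
#' @return A `data.frame` with columns `name`, `snr_lo`, `snr_hi` and the
#'   eight pattern bits `u1`..`u8`. Bands are left-closed/right-open except
#'   the top band, which is closed.
#' @export
environment_specs <- function() {
  codebook <- rbind(
    restaurant         = c(1, 1, 1, 1, 0, 0, 0, 0),
    cafe               = c(0, 0, 0, 0, 1, 1, 1, 1),
    `public transport` = c(1, 1, 0, 0, 1, 1, 0, 0),
    `pedestrian area`  = c(0, 0, 1, 1, 0, 0, 1, 1),
    home               = c(1, 0, 1, 0, 1, 0, 1, 0))
  edges <- seq(-12, 12, length.out = 6)
  out <- data.frame(name = rownames(codebook),
                    snr_lo = edges[1:5], snr_hi = edges[2:6],
                    row.names = NULL, check.names = FALSE)
  colnames(codebook) <- paste0("u", 1:8)
  cbind(out, as.data.frame(codebook, row.names = FALSE))
}

#' Environment lookup for a nominal SNR
#'
#' Deterministic band lookup: restaurant `[-12, -7.2)`, cafe `[-7.2, -2.4)`,
#' public transport `[-2.4, 2.4)`, pedestrian area `[2.4, 7.2)`, home
#' `[7.2, 12]`.
#'
#' @param snr_db SNR in dB, inside `[-12, 12]`.
#' @return One-row `data.frame` as in [environment_specs()].
#' @export
#' @examples
#' env_for_snr(-12)$name  # restaurant
env_for_snr <- function(snr_db) {
  stopifnot(length(snr_db) == 1, is.finite(snr_db))
  if (snr_db < -12 || snr_db > 12)
    stop("SNR out of range: must lie in [-12, 12] dB")
  specs <- environment_specs()
  band <- min(findInterval(snr_db, c(specs$snr_lo, 12)), nrow(specs))
  specs[band, ]
}

ucf_pattern <- function(env_row) as.numeric(env_row[paste0("u", 1:8)])

#' Mix a noise vector into a clean vector at a nominal SNR
#'
#' Rescales the noise so that `10 * log10(P_clean / P_noise) = snr_db`
#' (powers are mean squares) and returns `clean + scaled noise`.
#'
#' @param clean,noise numeric vectors of equal length with non-zero power.
#' @param snr_db nominal signal-to-noise ratio in dB.
#' @return Noisy vector of the same length.
#' @export
mix_at_snr <- function(clean, noise, snr_db) {
  stopifnot(length(clean) == length(noise))
  p_clean <- mean(clean^2)
  p_noise <- mean(noise^2)
  if (p_clean == 0) stop("zero-power clean signal")
  if (p_noise == 0) stop("zero-power noise signal")
  clean + noise * sqrt(p_clean / (p_noise * 10^(snr_db / 10)))
}

#' Empirical SNR of a noisy signal against its clean reference
#'
#' @param clean,noisy numeric vectors of equal length.
#' @return SNR in dB of `clean` against the residual `noisy - clean`.
#' @export
empirical_snr <- function(clean, noisy) {
  10 * log10(mean(clean^2) / mean((noisy - clean)^2))
}

#' Segment a signal into overlapping frames
#'
#' Frame length is `round(sample_rate * frame_ms / 1000)` samples and the
#' hop is `round(increment_pct / 100 * frame_length)` samples (the increment
#' rate is the fraction of a frame advanced between consecutive frames; at
#' 62.5% consecutive frames overlap by 37.5%). A trailing partial frame is
#' discarded.
#'
#' @param signal numeric vector.
#' @param sample_rate sampling rate in Hz.
#' @param frame_ms frame length in milliseconds.
#' @param increment_pct frame increment as a percentage of the frame length.
#' @return Matrix with one frame per row (0 rows if the signal is shorter
#'   than one frame).
#' @export
#' @examples
#' nrow(frame_signal(numeric(10000), 50000, 16, 62.5))  # 19 frames
frame_signal <- function(signal, sample_rate, frame_ms, increment_pct) {
  stopifnot(sample_rate > 0, frame_ms > 0, increment_pct > 0)
  frame_len <- round(sample_rate * frame_ms / 1000)
  hop <- round(increment_pct / 100 * frame_len)
  if (hop == 0) stop("hop is zero: increment too small for this frame length")
  if (length(signal) < frame_len)
    return(matrix(numeric(0), nrow = 0, ncol = frame_len))
  n_frames <- floor((length(signal) - frame_len) / hop) + 1
  starts <- (seq_len(n_frames) - 1) * hop
  t(vapply(starts, function(s) signal[(s + 1):(s + frame_len)],
           numeric(frame_len)))
}

#' Default generation parameters for the synthetic multimodal dataset
#'
#' @param n_sequences number of independent sequences.
#' @param seq_len records (time frames) per sequence.
#' @param feature_dim dimension of the clean and RF feature vectors.
#' @param lcf_dim dimension of the LCF feature vectors.
#' @param ar_coef temporal-smoothness coefficient of the per-dimension AR(1)
#'   clean process, in `[0, 1)`.
#' @param lcf_noise_sd standard deviation of the additive LCF noise.
#'   It is independent of the acoustic SNR (the visual stream is unaffected
#'   by acoustic noise), and its default places the visual stream's
#'   reliability between the noisy and clean acoustic extremes, so the
#'   streams cross over near mid-range SNR: the visual stream beats the
#'   audio stream in loud environments and loses to it in quiet ones, the
#'   regime audio-visual perception studies describe.
#' @param target_coef index of the clean coefficient used as the prediction
#'   target.
#' @param snr_levels nominal SNR levels (dB) assigned to sequences in a
#'   balanced rotation, the usual multi-condition mixing design; defaults
#'   to the nine levels -12, -9, ..., 12.
#' @return Named list of parameters.
#' @export
dataset_params <- function(n_sequences = 30, seq_len = 20, feature_dim = 4,
                           lcf_dim = 4, ar_coef = 0.9, lcf_noise_sd = 0.7,
                           target_coef = 1,
                           snr_levels = seq(-12, 12, by = 3)) {
  stopifnot(n_sequences >= 1, seq_len >= 1, feature_dim >= 1, lcf_dim >= 1,
            ar_coef >= 0, ar_coef < 1, lcf_noise_sd >= 0,
            target_coef >= 1, target_coef <= feature_dim,
            length(snr_levels) >= 1, all(snr_levels >= -12),
            all(snr_levels <= 12))
  list(n_sequences = as.integer(n_sequences), seq_len = as.integer(seq_len),
       feature_dim = as.integer(feature_dim), lcf_dim = as.integer(lcf_dim),
       ar_coef = ar_coef, lcf_noise_sd = lcf_noise_sd,
       target_coef = as.integer(target_coef), snr_levels = snr_levels)
}

#' Generate a synthetic multimodal dataset
#'
#' Emulates the statistical structure of an audio-visual speech task in
#' feature space. Per sequence: a clean feature sequence follows a smooth
#' stationary AR(1) process per dimension; the noisy RF stream is the clean
#' sequence mixed with broadband Gaussian noise at a nominal SNR taken from
#' the balanced rotation over `snr_levels` (so the empirical per-sequence
#' SNR equals the nominal one exactly and every noise condition is equally
#' represented); the LCF stream is a fixed random linear map of the
#' clean features plus Gaussian noise of `lcf_noise_sd` (its reliability is
#' independent of the acoustic environment, like lip movements unaffected by
#' acoustic noise); the UCF pattern is the deterministic environment code of
#' the nominal SNR band; the target is one chosen clean coefficient, min-max
#' scaled into `[0.05, 0.95]` over the dataset. Identical parameters and
#' seed reproduce the dataset bit for bit.
#'
#' @param params a [dataset_params()] list.
#' @param seed integer seed.
#' @return A `data.frame` of class `synthetic_dataset`, one row per record,
#'   with columns `seq`, `t`, `env`, `snr_db`, `target`, `clean_*`, `rf_*`,
#'   `lcf_*`, `ucf_1`..`ucf_8`, and attributes `params` (including the
#'   target scaling bounds), `lcf_map` and `seed`.
#' @export
generate_dataset <- function(params = dataset_params(), seed = 0) {
  p <- params
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  lcf_map <- matrix(stats::rnorm(p$lcf_dim * p$feature_dim) /
                      sqrt(p$feature_dim), p$lcf_dim, p$feature_dim)
  innov_sd <- sqrt(1 - p$ar_coef^2)   # stationary unit variance
  recs <- vector("list", p$n_sequences)
  for (s in seq_len(p$n_sequences)) {
    snr <- p$snr_levels[(s - 1) %% length(p$snr_levels) + 1]
    env <- env_for_snr(snr)
    clean <- matrix(0, p$seq_len, p$feature_dim)
    clean[1, ] <- stats::rnorm(p$feature_dim)
    if (p$seq_len > 1) for (t in 2:p$seq_len)
      clean[t, ] <- p$ar_coef * clean[t - 1, ] +
        innov_sd * stats::rnorm(p$feature_dim)
    noise <- matrix(stats::rnorm(p$seq_len * p$feature_dim),
                    p$seq_len, p$feature_dim)
    rf <- matrix(mix_at_snr(as.vector(clean), as.vector(noise), snr),
                 p$seq_len, p$feature_dim)
    lcf <- clean %*% t(lcf_map) +
      p$lcf_noise_sd * matrix(stats::rnorm(p$seq_len * p$lcf_dim),
                              p$seq_len, p$lcf_dim)
    ucf <- matrix(ucf_pattern(env), p$seq_len, 8, byrow = TRUE)
    recs[[s]] <- data.frame(
      seq = s, t = seq_len(p$seq_len), env = env$name, snr_db = snr,
      clean = I(clean), rf = I(rf), lcf = I(lcf), ucf = I(ucf))
  }
  df <- do.call(rbind, recs)
  out <- data.frame(seq = df$seq, t = df$t, env = df$env,
                    snr_db = df$snr_db)
  raw_target <- df$clean[, p$target_coef]
  t_lo <- min(raw_target); t_hi <- max(raw_target)
  out$target <- if (t_hi > t_lo)
    0.05 + 0.9 * (raw_target - t_lo) / (t_hi - t_lo) else rep(0.5, nrow(df))
  add_block <- function(m, prefix) {
    colnames(m) <- paste0(prefix, "_", seq_len(ncol(m)))
    m
  }
  out <- cbind(out, add_block(unclass(df$clean), "clean"),
               add_block(unclass(df$rf), "rf"),
               add_block(unclass(df$lcf), "lcf"),
               add_block(unclass(df$ucf), "ucf"))
  p$target_lo <- t_lo
  p$target_hi <- t_hi
  attr(out, "params") <- p
  attr(out, "lcf_map") <- lcf_map
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("synthetic_dataset", "data.frame")
  out
}

#' Columns of a dataset belonging to one feature block
#'
#' @param dataset a `synthetic_dataset` (or compatible data frame).
#' @param prefix one of `"clean"`, `"rf"`, `"lcf"`, `"ucf"`.
#' @return Numeric matrix of the block's columns.
#' @export
feature_block <- function(dataset, prefix) {
  cols <- grep(paste0("^", prefix, "_\\d+$"), names(dataset), value = TRUE)
  if (!length(cols)) stop("no columns with prefix ", prefix)
  as.matrix(dataset[, cols, drop = FALSE])
}

#' Write / read a synthetic dataset as CSV with a JSON parameter sidecar
#'
#' The records go to `path` as plain CSV; the generation parameters and seed
#' go to `<path>.json`.
#'
#' @param dataset a `synthetic_dataset`.
#' @param path CSV file path.
#' @return `path` invisibly / a `synthetic_dataset` (the LCF map is not
#'   restored by reading).
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  side <- list(params = attr(dataset, "params"),
               seed = attr(dataset, "seed"))
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE)
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    attr(out, "params") <- side$params
    attr(out, "seed") <- side$seed
  }
  class(out) <- c("synthetic_dataset", "data.frame")
  out
}
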