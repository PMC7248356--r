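#' Sentence bookkeeping of the five-speaker audio-visual corpus subset
#'
#' The package ships the printed per-speaker sentence counts of the
#' five-speaker corpus subset used for the audio-visual task (full and
#' aligned sentence counts, and the train/validation/test split) as a small
#' CSV. This function reads the table and recomputes the totals, so the
#' printed grand totals can be checked as plain arithmetic.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return List with `per_speaker` (the table, with a recomputed per-speaker
#'   `total`) and `totals` (named vector: train, validation, test, total).
#' @export
#' @examples
#' sentence_count_summary()$totals["total"]  # 4734
sentence_count_summary <- function(path = system.file(
  "extdata", "grid_sentence_counts.csv", package = "cannets")) {
  tab <- utils::read.csv(path)
  tab$total <- tab$train + tab$validation + tab$test
  stopifnot(all(tab$total == tab$used_aligned))
  totals <- c(train = sum(tab$train), validation = sum(tab$validation),
              test = sum(tab$test), total = sum(tab$total))
  list(per_speaker = tab, totals = totals)
}
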