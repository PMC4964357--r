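#' Write a task session as a TSV trial/event table with JSON metadata
#'
#' The trial table (onset seconds, sample index at a chosen rate, trial
#' index, condition, payoff, correctness) goes to `<path>.tsv`; session
#' metadata (participant, profile, paradigm, seed, cumulative feedback
#' times, configuration) to `<path>.json`.
#'
#' @param session a `task_session`.
#' @param path output path without extension.
#' @param fs sampling rate used for the `sample` column (default 1024).
#' @return invisibly, the two file paths.
#' @export
write_session_tsv <- function(session, path, fs = 1024) {
  tr <- session$trials
  tab <- data.frame(onset_s = tr$feedback_onset,
                    sample = round(tr$feedback_onset * fs) + 1L,
                    trial_index = tr$index, condition = tr$condition,
                    payoff = tr$payoff,
                    correct = if ("control_question_correct" %in% names(tr))
                      tr$control_question_correct else TRUE)
  tsv <- paste0(path, ".tsv"); js <- paste0(path, ".json")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(participant_id = session$participant_id,
               group_profile = session$group_profile,
               paradigm = session$paradigm, seed = session$seed,
               n_trials = nrow(tr),
               cumulative_feedback_times = session$cumulative_feedback_times,
               fs = fs)
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv = tsv, json = js))
}

#' Read a task session trial/event table written by [write_session_tsv()]
#'
#' @param path path without extension.
#' @return list with `trials` (data frame) and `meta` (list).
#' @export
read_session_tsv <- function(path) {
  trials <- utils::read.table(paste0(path, ".tsv"), sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  list(trials = trials, meta = meta)
}

#' Write the event table of a continuous recording as TSV
#'
#' @param eeg an `eeg_continuous`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_events_tsv <- function(eeg, path) {
  utils::write.table(eeg$events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a waveform test result as JSON (plus a significance-mask TSV)
#'
#' @param test a `fern_test`.
#' @param path output path without extension.
#' @return invisibly, the two file paths.
#' @export
write_test_json <- function(test, path) {
  js <- paste0(path, ".json"); tsv <- paste0(path, ".tsv")
  jsonlite::write_json(list(
    n = test$n, n_resamples = test$n_resamples,
    null_method = test$null_method, alpha = test$alpha, seed = test$seed,
    max_diff = test$max_diff, p_omnibus = test$p_omnibus,
    extents_ms = apply(test$extents_ms, 1, function(r)
      list(start = r[[1]], end = r[[2]]))),
    js, auto_unbox = TRUE, digits = NA)
  utils::write.table(
    data.frame(time_ms = test$time_ms, t = test$t_obs, p = test$p,
               significant = test$mask),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(json = js, tsv = tsv))
}
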