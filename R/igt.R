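#' Configuration for the child Iowa Gambling Task (two-deck, two-version)
#'
#' Each task version presents two decks that differ in long-term profit
#' (advantageous, AD, positive expected value; disadvantageous, DD, negative)
#' and in loss frequency (exactly one high-loss-frequency deck per version).
#' Every card pays a constant win; on loss trials an additional, larger loss
#' is applied so the net outcome is negative. The win amount and frequency
#' are identical across versions; loss amounts and frequencies differ across
#' decks and versions. Cumulative feedback is shown after every
#' `block_len` choices.
#'
#' @param n_trials_per_version trials per version (default 160).
#' @param block_len choices between cumulative-feedback displays (default 20).
#' @param initial_capital starting capital in currency units (default 120).
#' @param n_versions number of versions played (default 2).
#' @param deck_schedules data frame with one row per (version, deck):
#'   columns `version`, `deck` ("AD"/"DD"), `win_amount`, `win_freq`,
#'   `loss_amount` (gross, positive), `loss_freq`, `high_loss_freq` (logical).
#'   Defaults satisfy all structural constraints above.
#' @param strict enforce the economic structure (AD/DD expected-value signs,
#'   one high-loss-frequency deck per version, shared win schedule)?
#'   `FALSE` permits degenerate schedules, e.g. all payoffs zero, for
#'   testing capital bookkeeping; frequency range checks always apply.
#' @return list of class `igt_config`.
#' @export
igt_config <- function(n_trials_per_version = 160, block_len = 20,
                       initial_capital = 120, n_versions = 2,
                       deck_schedules = NULL, strict = TRUE) {
  if (is.null(deck_schedules)) {
    deck_schedules <- data.frame(
      version = c(1L, 1L, 2L, 2L),
      deck = c("AD", "DD", "AD", "DD"),
      win_amount = 5, win_freq = 1,
      loss_amount = c(30, 12, 7.5, 70),
      loss_freq = c(0.10, 0.60, 0.50, 0.10),
      high_loss_freq = c(FALSE, TRUE, TRUE, FALSE)
    )
  }
  cfg <- list(n_trials_per_version = n_trials_per_version,
              block_len = block_len, initial_capital = initial_capital,
              n_versions = n_versions, deck_schedules = deck_schedules,
              strict = strict)
  class(cfg) <- "igt_config"
  validate_igt_config(cfg)
  cfg
}

validate_igt_config <- function(cfg) {
  ds <- cfg$deck_schedules
  if (any(ds$win_freq < 0 | ds$win_freq > 1 | ds$loss_freq < 0 | ds$loss_freq > 1))
    stop_cfg("configuration error: win/loss frequencies must lie in [0, 1]")
  if (!is_count(cfg$n_trials_per_version) || !is_count(cfg$block_len))
    stop_cfg("configuration error: trial and block counts must be positive integers")
  if (identical(cfg$strict, FALSE)) return(invisible(cfg))
  ev <- ds$win_amount * ds$win_freq - ds$loss_amount * ds$loss_freq
  for (v in unique(ds$version)) {
    sub <- ds[ds$version == v, ]
    if (any(ev[ds$version == v][sub$deck == "AD"] <= 0) ||
        any(ev[ds$version == v][sub$deck == "DD"] >= 0))
      stop_cfg("configuration error: AD decks must have positive and DD decks negative expected payoff (version %s)", v)
    if (sum(sub$high_loss_freq) != 1L)
      stop_cfg("configuration error: exactly one high-loss-frequency deck per version (version %s)", v)
  }
  if (length(unique(ds$win_amount)) != 1L || length(unique(ds$win_freq)) != 1L)
    stop_cfg("configuration error: win amount and frequency must be identical across decks/versions")
  invisible(cfg)
}

#' Simulate one child-IGT session
#'
#' Plays `n_versions` versions of `n_trials_per_version` choices each,
#' tracking running capital from the initial endowment and inserting a
#' cumulative-feedback display after every `block_len` choices. Two fixed
#' choice policies are available: `"uniform-random"`, and
#' `"loss-frequency-avoidant"`, the children's dominant strategy of avoiding
#' both the disadvantageous deck and high-loss-frequency options (each
#' unfavourable attribute halves a deck's selection weight).
#'
#' @param config an [igt_config()].
#' @param policy `"loss-frequency-avoidant"` (default) or `"uniform-random"`.
#' @param seed integer seed; the session is fully reproducible.
#' @param participant_id,group_profile metadata carried through to the EEG
#'   synthesis stage (`group_profile` one of "control", "ADHD", "ASD").
#' @param iti_range inter-trial interval jitter range in seconds.
#' @return A `task_session` object: trial table (`$trials`) with onset times,
#'   deck attributes, win/loss outcome, payoff and running capital, plus
#'   cumulative feedback times and metadata.
#' @examples
#' s <- simulate_igt_session(igt_config(n_versions = 1), seed = 1)
#' nrow(s$trials)                      # 160
#' length(s$cumulative_feedback_times) # 8
#' @export
simulate_igt_session <- function(config = igt_config(),
                                 policy = c("loss-frequency-avoidant",
                                            "uniform-random"),
                                 seed = 1L, participant_id = "sim",
                                 group_profile = "control",
                                 iti_range = c(1.5, 2.5)) {
  validate_igt_config(config)
  policy <- match.arg(policy)
  ds <- config$deck_schedules
  n_v <- config$n_trials_per_version
  with_seed(seed, {
    rows <- vector("list", config$n_versions)
    t_now <- 0
    cfb <- numeric(0)
    capital <- config$initial_capital
    idx0 <- 0L
    for (v in seq_len(config$n_versions)) {
      sub <- ds[ds$version == v, ]
      w <- if (policy == "uniform-random") rep(1, nrow(sub)) else
        0.5^((sub$deck == "DD") + sub$high_loss_freq)
      pick <- sample.int(nrow(sub), n_v, replace = TRUE, prob = w / sum(w))
      win <- stats::runif(n_v) < sub$win_freq[pick]
      lost <- stats::runif(n_v) < sub$loss_freq[pick]
      payoff <- ifelse(win, sub$win_amount[pick], 0) -
        ifelse(lost, sub$loss_amount[pick], 0)
      iti <- stats::runif(n_v, iti_range[1], iti_range[2])
      onset <- numeric(n_v)
      for (i in seq_len(n_v)) {
        t_now <- t_now + iti[i]
        onset[i] <- t_now
        t_now <- t_now + 1.0                  # feedback display
        if (i %% config$block_len == 0L) {
          t_now <- t_now + 4.0                # cumulative feedback display
          cfb <- c(cfb, t_now)
        }
      }
      capital_after <- capital + cumsum(payoff)
      capital <- capital_after[n_v]
      rows[[v]] <- data.frame(
        index = idx0 + seq_len(n_v), paradigm = "IGT", version = v,
        deck = sub$deck[pick], is_DD = sub$deck[pick] == "DD",
        high_loss_freq = sub$high_loss_freq[pick],
        option = sprintf("v%d_%s", v, sub$deck[pick]),
        outcome = ifelse(lost, "loss", "win"),
        payoff = payoff, capital_after = capital_after,
        feedback_onset = onset, usable = TRUE,
        stringsAsFactors = FALSE)
      idx0 <- idx0 + n_v
    }
    trials <- do.call(rbind, rows)
    trials$condition <- paste(trials$outcome, trials$option, sep = "_")
    trials$gain_key <- trials$outcome
    session <- list(participant_id = participant_id,
                    group_profile = group_profile, paradigm = "IGT",
                    config = config, policy = policy, trials = trials,
                    cumulative_feedback_times = cfb,
                    final_capital = capital, seed = seed)
    class(session) <- c("igt_session", "task_session")
    session
  })
}

#' @export
print.task_session <- function(x, ...) {
  cat(sprintf("<%s session> participant %s (%s): %d trials, %d cumulative feedbacks\n",
              x$paradigm, x$participant_id, x$group_profile,
              nrow(x$trials), length(x$cumulative_feedback_times)))
  if (x$paradigm == "IGT")
    cat(sprintf("  final capital: %.1f (initial %.1f)\n",
                x$final_capital, x$config$initial_capital))
  invisible(x)
}

# Trial subsets entering the two monetary contrasts: the disadvantageous
# decks, and the high-loss-frequency decks (one deck overlaps by design).
igt_option_trials <- function(session, option_type = c("DD", "highfreq")) {
  option_type <- match.arg(option_type)
  tr <- session$trials
  if (option_type == "DD") tr[tr$is_DD, , drop = FALSE]
  else tr[tr$high_loss_freq, , drop = FALSE]
}
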