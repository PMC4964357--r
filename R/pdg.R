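#' Configuration for the rigged observed Prisoner's Dilemma Game
#'
#' Participants watch two virtual players. The game is rigged: the fair
#' player cooperates on an exact fraction of trials (default 72.5%, i.e.
#' betrays on 27.5%) and the unfair player betrays on an exact fraction
#' (default 67.5%). The participant is paid according to the fair player's
#' choices: 3 points when that player cooperates, 6 when he betrays. A
#' standard T>R>P>S matrix additionally books both players' game points.
#' A control question follows each trial; only correctly answered trials
#' are analysed downstream.
#'
#' @param n_trials total trials (default 160).
#' @param cumulative_block trials between cumulative outcome displays
#'   (default 40).
#' @param fair_coop_rate,unfair_betray_rate rigged policy rates in \[0, 1\].
#' @param payoff_fair named numeric: participant points for the fair
#'   player's `cooperate` and `betray` choices (defaults 3 and 6).
#' @param payoff_matrix 2x2 game-point matrix for a single player,
#'   rows = own action (cooperate, betray), cols = other's action.
#' @param control_question_error_rate probability of an incorrect/omitted
#'   control-question response (simulated inattention).
#' @return list of class `pdg_config`.
#' @export
pdg_config <- function(n_trials = 160, cumulative_block = 40,
                       fair_coop_rate = 0.725, unfair_betray_rate = 0.675,
                       payoff_fair = c(cooperate = 3, betray = 6),
                       payoff_matrix = matrix(c(3, 6, 0, 1), 2, 2,
                         dimnames = list(c("cooperate", "betray"),
                                         c("cooperate", "betray"))),
                       control_question_error_rate = 0.05) {
  cfg <- list(n_trials = n_trials, cumulative_block = cumulative_block,
              fair_coop_rate = fair_coop_rate,
              unfair_betray_rate = unfair_betray_rate,
              payoff_fair = payoff_fair, payoff_matrix = payoff_matrix,
              control_question_error_rate = control_question_error_rate)
  class(cfg) <- "pdg_config"
  validate_pdg_config(cfg)
  cfg
}

validate_pdg_config <- function(cfg) {
  check_proportion(cfg$fair_coop_rate, "fair_coop_rate")
  check_proportion(cfg$unfair_betray_rate, "unfair_betray_rate")
  check_proportion(cfg$control_question_error_rate,
                   "control_question_error_rate")
  if (!is_count(cfg$n_trials) || !is_count(cfg$cumulative_block))
    stop_cfg("configuration error: trial and block counts must be positive integers")
  if (cfg$payoff_fair[["betray"]] <= cfg$payoff_fair[["cooperate"]])
    stop_cfg("configuration error: fair-player betrayal must pay more than cooperation")
  invisible(cfg)
}

#' Simulate one observed Prisoner's Dilemma session
#'
#' The rigging is realised as exact counts: the fair player cooperates on
#' exactly `round(fair_coop_rate * n_trials)` trials and the unfair player
#' betrays on exactly `round(unfair_betray_rate * n_trials)` trials, with
#' trial order permuted by the seed. The feedback-locked event of each trial
#' is the onset after both players' choices are revealed. Control-question
#' correctness is drawn independently per trial; incorrect trials are marked
#' unusable for epoching.
#'
#' @inheritParams simulate_igt_session
#' @param config a [pdg_config()].
#' @return A `task_session` object whose trial table carries both players'
#'   actions, the participant payoff (fair player's points), condition label
#'   (= fair player's action), feedback onsets and control-question results.
#' @examples
#' s <- simulate_pdg_session(pdg_config(), seed = 1)
#' sum(s$trials$fair_action == "cooperate")  # 116 of 160
#' @export
simulate_pdg_session <- function(config = pdg_config(), seed = 1L,
                                 participant_id = "sim",
                                 group_profile = "control",
                                 iti_range = c(1.5, 2.5)) {
  validate_pdg_config(config)
  n <- config$n_trials
  with_seed(seed, {
    n_coop <- round(config$fair_coop_rate * n)
    n_betray <- round(config$unfair_betray_rate * n)
    fair <- sample(rep(c("cooperate", "betray"), c(n_coop, n - n_coop)))
    unfair <- sample(rep(c("betray", "cooperate"), c(n_betray, n - n_betray)))
    payoff <- unname(config$payoff_fair[fair])
    fair_points <- config$payoff_matrix[cbind(fair, unfair)]
    unfair_points <- config$payoff_matrix[cbind(unfair, fair)]
    correct <- stats::runif(n) >= config$control_question_error_rate
    iti <- stats::runif(n, iti_range[1], iti_range[2])
    onset <- numeric(n); cfb <- numeric(0); t_now <- 0
    for (i in seq_len(n)) {
      t_now <- t_now + iti[i] + 1.0 + 1.0   # ITI + first face + second face
      onset[i] <- t_now                     # both players' choices visible
      t_now <- t_now + 1.0 + 2.0            # outcome view + control question
      if (i %% config$cumulative_block == 0L) {
        t_now <- t_now + 4.0
        cfb <- c(cfb, t_now)
      }
    }
    trials <- data.frame(
      index = seq_len(n), paradigm = "PDG",
      fair_action = fair, unfair_action = unfair,
      condition = fair, gain_key = fair, payoff = payoff,
      fair_points = fair_points, unfair_points = unfair_points,
      control_question_correct = correct, usable = correct,
      feedback_onset = onset, stringsAsFactors = FALSE)
    session <- list(participant_id = participant_id,
                    group_profile = group_profile, paradigm = "PDG",
                    config = config, trials = trials,
                    cumulative_feedback_times = cfb, seed = seed)
    class(session) <- c("pdg_session", "task_session")
    session
  })
}

#' Screen sessions for extreme control-question omission errors
#'
#' Sessions whose proportion of incorrect/omitted control-question responses
#' strictly exceeds `threshold` (default 70%) are excluded, reflecting poor
#' attention or task understanding; in retained sessions only correctly
#' answered trials remain usable for epoching.
#'
#' @param sessions a list of PDG `task_session` objects (a single session is
#'   accepted).
#' @param threshold exclusion threshold on the omission-error proportion;
#'   exclusion requires strictly greater than this value.
#' @return list with `retained` and `excluded` session lists and a data frame
#'   `omission_rates` (participant, error rate, retained flag).
#' @export
filter_participants_by_omission <- function(sessions, threshold = 0.70) {
  if (inherits(sessions, "task_session")) sessions <- list(sessions)
  check_proportion(threshold, "threshold")
  rates <- vapply(sessions, function(s) {
    if (!identical(s$paradigm, "PDG"))
      stop_cfg("paradigm error: omission screening applies to PDG sessions only")
    mean(!s$trials$control_question_correct)
  }, numeric(1))
  keep <- rates <= threshold
  data.frame(participant = vapply(sessions, `[[`, "", "participant_id"),
             omission_rate = rates, retained = keep) -> tab
  list(retained = sessions[keep], excluded = sessions[!keep],
       omission_rates = tab)
}
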