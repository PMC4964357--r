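#' Study configuration for simulated multi-group cohorts
#'
#' Bundles every stage's configuration for an end-to-end simulated study:
#' group sizes and generator profiles, task parameters, synthesis
#' parameters, preprocessing, waveform statistics and source analysis.
#' Per-subject seeds are derived deterministically from the master seed.
#'
#' @param groups named integer vector of subjects per group; names are
#'   generator profiles (default `c(control = 20, ADHD = 20, ASD = 20)`).
#' @param tasks tasks to run, subset of `c("IGT", "PDG")`.
#' @param igt,pdg task configurations ([igt_config()], [pdg_config()]).
#' @param n_scalp scalp channels in the montage (default 128).
#' @param fs synthesis sampling rate in Hz (default 1024).
#' @param noise_rms,blink_rate synthesis noise parameters
#'   (see [synthesize_eeg()]).
#' @param preproc a [preproc_config()].
#' @param analysis an [analysis_config()].
#' @param inverse an [inverse_config()].
#' @param run_source run the source-localization stage (default TRUE).
#' @param igt_policy IGT choice policy for all simulated participants.
#' @param test_unit sampling unit of the within-group condition contrasts:
#'   `"trials"` (default) pools surviving single-trial waveforms across the
#'   group's subjects, giving the large effective samples implied by
#'   published feedback-ERP t/d statistics; `"subjects"` enters per-subject
#'   condition-mean waveforms instead (conservative with respect to
#'   between-subject variability).
#' @param seed master seed.
#' @return list of class `study_config`.
#' @export
study_config <- function(groups = c(control = 20, ADHD = 20, ASD = 20),
                         tasks = c("IGT", "PDG"),
                         igt = igt_config(), pdg = pdg_config(),
                         n_scalp = 128, fs = 1024,
                         noise_rms = 10, blink_rate = 0.03,
                         preproc = preproc_config(),
                         analysis = analysis_config(),
                         inverse = inverse_config(),
                         run_source = TRUE,
                         igt_policy = "loss-frequency-avoidant",
                         test_unit = c("trials", "subjects"),
                         seed = 1L) {
  test_unit <- match.arg(test_unit)
  cfg <- list(groups = groups, tasks = tasks, igt = igt, pdg = pdg,
              n_scalp = n_scalp, fs = fs, noise_rms = noise_rms,
              blink_rate = blink_rate, preproc = preproc,
              analysis = analysis, inverse = inverse,
              run_source = run_source, igt_policy = igt_policy,
              test_unit = test_unit, seed = seed)
  class(cfg) <- "study_config"
  cfg
}

#' Validate a study configuration
#'
#' Checks every invariant of every sub-configuration; violations are
#' returned (not raised) and named by the offending path.
#'
#' @param cfg a [study_config()].
#' @return `"ok"` if valid, otherwise a character vector of violations.
#' @examples
#' validate_config(study_config())                      # "ok"
#' cfg <- study_config(); cfg$analysis$fern_window <- c(500, 400)
#' validate_config(cfg)
#' @export
validate_config <- function(cfg) {
  v <- character(0)
  grab <- function(path, expr) {
    msg <- tryCatch({ force(expr); NULL }, error = function(e)
      paste0(path, ": ", conditionMessage(e)))
    if (!is.null(msg)) v <<- c(v, msg)
  }
  if (length(cfg$groups) == 0L || any(cfg$groups < 1) ||
      any(cfg$groups != round(cfg$groups)))
    v <- c(v, "groups: subject counts must be positive integers")
  if (is.null(names(cfg$groups)) ||
      !all(names(cfg$groups) %in% c("control", "ADHD", "ASD")))
    v <- c(v, "groups: names must be generator profiles (control/ADHD/ASD)")
  if (!all(cfg$tasks %in% c("IGT", "PDG")) || length(cfg$tasks) == 0L)
    v <- c(v, "tasks: must be a non-empty subset of IGT, PDG")
  grab("igt", validate_igt_config(cfg$igt))
  grab("pdg", validate_pdg_config(cfg$pdg))
  grab("preproc", validate_preproc_config(cfg$preproc))
  fw <- cfg$analysis$fern_window
  if (fw[1] >= fw[2]) v <- c(v, "analysis$fern_window: window reversed")
  if (cfg$analysis$alpha <= 0 || cfg$analysis$alpha >= 1)
    v <- c(v, "analysis$alpha: must lie in (0, 1)")
  if (cfg$inverse$depth_exponent < 0)
    v <- c(v, "inverse$depth_exponent: must be >= 0")
  if (cfg$noise_rms < 0) v <- c(v, "noise_rms: must be non-negative")
  if (cfg$fs <= 0 || cfg$preproc$target_fs > cfg$fs)
    v <- c(v, "fs: synthesis rate must be positive and >= preproc target_fs")
  if (length(v) == 0L) "ok" else v
}

# Option labels entering each monetary contrast, from the deck schedule.
igt_contrast_labels <- function(igt_cfg, option_type = c("DD", "highfreq")) {
  option_type <- match.arg(option_type)
  ds <- igt_cfg$deck_schedules
  sel <- if (option_type == "DD") ds$deck == "DD" else ds$high_loss_freq
  opts <- sprintf("v%d_%s", ds$version[sel], ds$deck[sel])
  list(loss = paste0("loss_", opts), win = paste0("win_", opts))
}

#' Run a full simulated study
#'
#' Executes simulate -> synthesize -> preprocess -> ERP statistics (->
#' source analysis) for every subject of every group and task, then builds
#' the Results-style grid: within-group condition contrasts (loss vs win for
#' the disadvantageous and the high-loss-frequency options; betrayal vs
#' cooperation) tested across subjects with the bootstrap Monte Carlo test,
#' between-group ACC ROI contrasts via Mann-Whitney, trial-retention tables
#' and demographic covariate checks on simulated ages/genders.
#'
#' ROI activation is reported fERN-aligned: the sign is flipped so that a
#' generator producing the typical negative frontocentral deflection for
#' the more salient condition yields a positive loss-minus-win (or
#' betrayal-minus-cooperation) activation.
#'
#' @param cfg a [study_config()]; invalid configurations abort with the
#'   full violation list.
#' @return object of class `fern_study`: `contrasts[[group]][[task]]`
#'   (`fern_test`s per option type), `fern_amplitudes`, `roi` (per-subject
#'   scalars), `group_comparisons`, `retention`, `covariates`, `subjects`,
#'   and full config/seed provenance.
#' @export
run_study <- function(cfg = study_config()) {
  ok <- validate_config(cfg)
  if (!identical(ok, "ok"))
    stop_cfg("config error:\n%s", paste("-", ok, collapse = "\n"))
  montage <- spherical_montage(cfg$n_scalp)
  model <- sphere_model()
  space <- if (cfg$run_source) source_space(model) else NULL
  lead <- if (cfg$run_source) build_spherical_leadfield(montage, space) else NULL
  acfg <- cfg$analysis
  contrast_defs <- list(
    IGT = list(DD = igt_contrast_labels(cfg$igt, "DD"),
               highfreq = igt_contrast_labels(cfg$igt, "highfreq")),
    PDG = list(social = list(loss = "betray", win = "cooperate")))

  subjects <- list(); retention <- list()
  waves <- list(); roi <- list(); amps <- list()
  dropped <- data.frame(subject = character(0), task = character(0),
                        option_type = character(0))
  for (g in names(cfg$groups)) {
    for (j in seq_len(cfg$groups[[g]])) {
      sid <- sprintf("%s_%02d", g, j)
      demo_seed <- derive_seed(cfg$seed, paste0(sid, ":demo"))
      demo <- with_seed(demo_seed, list(age = stats::runif(1, 8, 15),
                                        gender = sample(c("M", "F"), 1)))
      subjects[[sid]] <- data.frame(subject = sid, group = g,
                                    age = demo$age, gender = demo$gender)
      for (task in cfg$tasks) {
        s_seed <- derive_seed(cfg$seed, paste0(sid, ":", task))
        session <- if (task == "IGT")
          simulate_igt_session(cfg$igt, policy = cfg$igt_policy,
                               seed = s_seed, participant_id = sid,
                               group_profile = g)
        else simulate_pdg_session(cfg$pdg, seed = s_seed,
                                  participant_id = sid, group_profile = g)
        if (task == "PDG" &&
            length(filter_participants_by_omission(session)$retained) == 0L)
          next  # excluded for extreme omission errors
        raw <- synthesize_eeg(session, erp_template(g), montage,
                              noise_rms = cfg$noise_rms,
                              blink_rate = cfg$blink_rate, fs = cfg$fs,
                              seed = derive_seed(cfg$seed, paste0(sid, ":eeg:", task)),
                              model = model, subject_gain = NA)
        ep <- preprocess_eeg(raw, cfg$preproc)
        retention[[paste(sid, task)]] <-
          cbind(subject = sid, task = task, ep$retention)
        for (ct in names(contrast_defs[[task]])) {
          labs <- contrast_defs[[task]][[ct]]
          # a subject without surviving epochs in a condition drops out of
          # this contrast (as in practice); logged under $dropped
          erpL <- tryCatch(average_condition(ep, labs$loss),
                           error = function(e) NULL)
          erpW <- tryCatch(average_condition(ep, labs$win),
                           error = function(e) NULL)
          if (is.null(erpL) || is.null(erpW)) {
            dropped <- rbind(dropped,
                             data.frame(subject = sid, task = task,
                                        option_type = ct))
            next
          }
          fz <- channel_index(montage, acfg$electrode)
          key <- paste(g, task, ct, sep = ".")
          if (cfg$test_unit == "trials") {
            waves[[key]]$loss <- rbind(waves[[key]]$loss,
                                       condition_trials(ep, labs$loss,
                                                        acfg$electrode))
            waves[[key]]$win <- rbind(waves[[key]]$win,
                                      condition_trials(ep, labs$win,
                                                       acfg$electrode))
          } else {
            waves[[key]]$loss <- rbind(waves[[key]]$loss, erpL$waveform[fz, ])
            waves[[key]]$win <- rbind(waves[[key]]$win, erpW$waveform[fz, ])
          }
          waves[[key]]$time_ms <- erpL$time_ms
          amps[[key]] <- rbind(amps[[key]], data.frame(
            subject = sid, group = g, task = task, option_type = ct,
            age = demo$age, gender = demo$gender,
            fern_loss = fern_amplitude(erpL, acfg),
            fern_win = fern_amplitude(erpW, acfg)))
          if (cfg$run_source) {
            diff_erp <- erpL
            diff_erp$waveform <- erpL$waveform - erpW$waveform
            src <- depth_weighted_min_norm(lead, diff_erp, cfg$inverse)
            roi[[key]] <- c(roi[[key]],
                            -roi_scalar(src, "ACC", acfg$fern_window))
          }
        }
      }
    }
  }
  # within-group contrasts across subjects
  contrasts <- list()
  for (key in names(waves)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    w <- waves[[key]]
    tcfg <- acfg
    tcfg$seed <- derive_seed(cfg$seed, paste0("test:", key))
    contrasts[[parts[1]]][[parts[2]]][[parts[3]]] <-
      montecarlo_bootstrap_test(w$loss, w$win, w$time_ms, tcfg)
  }
  # between-group ROI comparisons
  group_comparisons <- list()
  if (cfg$run_source) {
    gs <- names(cfg$groups)
    if (length(gs) >= 2) {
      for (task in cfg$tasks) for (ct in names(contrast_defs[[task]])) {
        for (i in seq_len(length(gs) - 1)) for (k in (i + 1):length(gs)) {
          ka <- paste(gs[i], task, ct, sep = "."); kb <- paste(gs[k], task, ct, sep = ".")
          if (is.null(roi[[ka]]) || is.null(roi[[kb]])) next
          group_comparisons[[paste(gs[i], "vs", gs[k], task, ct)]] <-
            mannwhitney_groups(roi[[ka]], roi[[kb]])
        }
      }
    }
  }
  amp_tab <- do.call(rbind, amps)
  rownames(amp_tab) <- NULL
  covariates <- lapply(split(amp_tab, amp_tab$group), function(d) {
    d1 <- d[d$option_type == d$option_type[1] & d$task == d$task[1], ]
    if (nrow(d1) >= 3)
      covariate_checks(d1$fern_loss - d1$fern_win, d1$age, d1$gender)
    else NULL
  })
  out <- list(config = cfg, contrasts = contrasts,
              fern_amplitudes = amp_tab,
              roi = roi, group_comparisons = group_comparisons,
              retention = do.call(rbind, retention),
              covariates = covariates, dropped = dropped,
              subjects = do.call(rbind, subjects), seed = cfg$seed)
  rownames(out$retention) <- rownames(out$subjects) <- NULL
  class(out) <- "fern_study"
  out
}

#' @export
print.fern_study <- function(x, ...) {
  cat(sprintf("<fern_study> %s subjects; tasks: %s; seed %s\n",
              paste(sprintf("%s=%d", names(x$config$groups), x$config$groups),
                    collapse = ", "),
              paste(x$config$tasks, collapse = ", "), format(x$seed)))
  for (g in names(x$contrasts)) for (task in names(x$contrasts[[g]]))
    for (ct in names(x$contrasts[[g]][[task]])) {
      r <- x$contrasts[[g]][[task]][[ct]]
      sig <- nrow(r$extents_ms) > 0
      cat(sprintf("  %-8s %s/%s: omnibus p = %.3f%s\n", g, task, ct,
                  r$p_omnibus,
                  if (sig) sprintf(", extents %s ms",
                                   paste(apply(round(r$extents_ms), 1, paste,
                                               collapse = "-"), collapse = ","))
                  else ""))
    }
  if (length(x$group_comparisons)) {
    cat("  ROI group comparisons:\n")
    for (nm in names(x$group_comparisons)) {
      gc <- x$group_comparisons[[nm]]
      cat(sprintf("    %-28s U = %5.1f, p = %.3f, r = %.2f\n",
                  nm, gc$U, gc$p, gc$r))
    }
  }
  invisible(x)
}

#' @export
summary.fern_study <- function(object, ...) {
  print(object)
  cat("\nMean fERN amplitudes (µV) by group/task/option:\n")
  a <- object$fern_amplitudes
  agg <- stats::aggregate(cbind(fern_loss, fern_win) ~ group + task + option_type,
                          data = a, FUN = mean)
  print(agg, row.names = FALSE)
  invisible(object)
}
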