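# Shared fixtures: small montages and scaled study configurations.
#
# Cohort-level simulations use variance-preserving downscaling: trial counts
# reduced by a factor k relative to the full task, trial noise reduced by
# sqrt(k), so each subject's condition-mean SNR matches the full design.
# Power batteries use mild scaling (k = 2) at the study's group sizes;
# null-calibration batteries, which are scale-free, use k = 8.

tiny_montage <- function(n = 8) spherical_montage(n)

# quick continuous-EEG object around a given data matrix (for filter tests)
raw_from_matrix <- function(data, fs, montage = NULL,
                            events = NULL) {
  if (is.null(montage)) montage <- spherical_montage(max(4, nrow(data) - 2))
  if (is.null(events))
    events <- data.frame(sample = min(100L, ncol(data)),
                         onset_s = min(100L, ncol(data)) / fs,
                         trial_index = 1L, condition = "x", usable = TRUE)
  structure(list(data = data, fs = fs, montage = montage, events = events),
            class = "eeg_continuous")
}

# scaled single-group cohort study (IGT), downscaling factor k
scaled_igt_study <- function(profile, seed, n_subjects = 22, k = 2,
                             n_resamples = 1000) {
  study_config(
    groups = stats::setNames(n_subjects, profile), tasks = "IGT",
    igt = igt_config(n_trials_per_version = 160 / k,
                     block_len = if (k <= 4) 20 else 10),
    n_scalp = 4, fs = 256, noise_rms = 10 / sqrt(k),
    analysis = analysis_config(n_resamples = n_resamples),
    run_source = FALSE, seed = seed)
}

# scaled single-group cohort study (PDG): k ~ 6.7 downscaling
scaled_pdg_study <- function(profile, seed, n_subjects = 28,
                             n_resamples = 1000) {
  study_config(
    groups = stats::setNames(n_subjects, profile), tasks = "PDG",
    pdg = pdg_config(n_trials = 24, cumulative_block = 12),
    n_scalp = 4, fs = 256, noise_rms = 10 / sqrt(160 / 24),
    analysis = analysis_config(n_resamples = n_resamples),
    run_source = FALSE, seed = seed)
}

# noiseless synthetic epochs for one profile/paradigm, via the full chain
noiseless_epochs <- function(profile = "control", paradigm = "IGT",
                             seed = 1) {
  session <- if (paradigm == "IGT")
    simulate_igt_session(igt_config(n_trials_per_version = 20, block_len = 10),
                         policy = "uniform-random", seed = seed,
                         group_profile = profile)
  else
    simulate_pdg_session(pdg_config(n_trials = 24, cumulative_block = 12),
                         seed = seed, group_profile = profile)
  raw <- synthesize_eeg(session, erp_template(profile), tiny_montage(),
                        noise_rms = 0, blink_rate = 0, fs = 256, seed = seed)
  ep <- extract_epochs(rereference_mastoids(raw))
  baseline_correct(ep)
}
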