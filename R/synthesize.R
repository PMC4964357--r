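#' Feedback-locked ERP template with group-dependent condition gains
#'
#' Describes the generator of the synthetic feedback-related negativity: a
#' negative Gaussian-windowed deflection with its peak inside the 250-400 ms
#' post-feedback window, produced by a single equivalent dipole at a deep
#' frontal-midline (ACC-proxy) location with radial orientation. Condition
#' gains encode the group profiles observed in the study population:
#' \itemize{
#'   \item control: losses > wins and betrayal > cooperation (in magnitude);
#'   \item ADHD: no condition modulation (uniformly reduced response);
#'   \item ASD: losses > wins but cooperation > betrayal (inverted social
#'     modulation).
#' }
#'
#' @param group_profile "control", "ADHD" or "ASD".
#' @param peak_latency_ms,width_ms Gaussian peak and SD in ms (defaults 310
#'   and 45).
#' @param base_amplitude_uv peak Fz amplitude in microvolts for a unit
#'   condition gain (negative; default -4).
#' @param gains named condition multipliers; defaults implement the profile
#'   patterns above.
#' @param dipole_pos ACC-proxy dipole location in metres (default
#'   `c(0, 0.025, 0.035)`, deep frontal midline).
#' @param subject_sd between-subject multiplicative amplitude jitter
#'   (lognormal SD on the log scale; default 0.2).
#' @return list of class `erp_template`.
#' @export
erp_template <- function(group_profile = c("control", "ADHD", "ASD"),
                         peak_latency_ms = 310, width_ms = 45,
                         base_amplitude_uv = -4, gains = NULL,
                         dipole_pos = c(0, 0.025, 0.035),
                         subject_sd = 0.2) {
  group_profile <- match.arg(group_profile)
  if (is.null(gains)) {
    gains <- switch(group_profile,
      control = c(win = 0.6, loss = 1.0, cooperate = 0.6, betray = 1.0),
      ADHD    = c(win = 0.6, loss = 0.6, cooperate = 0.6, betray = 0.6),
      ASD     = c(win = 0.6, loss = 1.0, cooperate = 1.0, betray = 0.6))
  }
  out <- list(group_profile = group_profile,
              peak_latency_ms = peak_latency_ms, width_ms = width_ms,
              base_amplitude_uv = base_amplitude_uv, gains = gains,
              dipole_pos = dipole_pos,
              dipole_ori = dipole_pos / sqrt(sum(dipole_pos^2)),
              subject_sd = subject_sd)
  class(out) <- "erp_template"
  out
}

# Template time course (unit peak) on a sample grid, seconds post-feedback.
template_waveform <- function(template, t_s) {
  exp(-0.5 * ((t_s * 1000 - template$peak_latency_ms) / template$width_ms)^2)
}

# 1/f-plus-white-floor noise, channels x samples, RMS-normalised per channel.
pink_noise <- function(n, fs, nch = 1L) {
  n_out <- n
  n <- stats::nextn(n, c(2, 3, 5))     # FFT-friendly length, then truncate
  f <- seq_len(n) * fs / n
  f <- pmin(f, fs - f + fs / n)        # fold to the symmetric spectrum
  amp <- sqrt(1 / f + 0.1)             # power ~ 1/f + white floor
  spec <- matrix(stats::rnorm(n * nch), n, nch) +
    1i * matrix(stats::rnorm(n * nch), n, nch)
  x <- Re(stats::mvfft(spec * amp, inverse = TRUE))[seq_len(n_out), , drop = FALSE]
  t(x) / apply(x, 2, stats::sd)
}

#' Synthesize feedback-locked continuous high-density EEG
#'
#' Renders a multichannel recording for one task session: at every feedback
#' onset the ERP template, scaled by the trial condition's gain for the
#' session's group profile, is forward-projected from the ACC-proxy dipole
#' through the spherical head model onto the sensors; 1/f-plus-white noise
#' (independent across channels) and optional frontal blink transients are
#' added. The projection is normalised so that the Fz peak amplitude of a
#' unit-gain response equals `base_amplitude_uv`. One event marker per
#' feedback onset carries the trial's condition label.
#'
#' @param session a `task_session`.
#' @param template an [erp_template()]; its profile must match the session's.
#' @param montage an [spherical_montage()].
#' @param noise_rms noise RMS per channel in microvolts (default 10; 0 gives
#'   a noiseless recording).
#' @param blink_rate expected blink rate in Hz (default 0.03; 0 disables).
#' @param fs sampling rate in Hz (default 1024).
#' @param seed integer seed.
#' @param model a [sphere_model()] for the forward projection.
#' @param duration_s recording length in seconds; default covers the session
#'   plus 2 s of padding. An error is raised if the session outlasts it.
#' @param subject_gain multiplicative subject-level amplitude factor
#'   (default 1; `NA` draws one from the template's between-subject
#'   distribution).
#' @return object of class `eeg_continuous`: `data` (channels x samples,
#'   microvolts), `fs`, `montage`, `events` (sample, onset_s, trial index,
#'   condition, usable flag), and provenance.
#' @export
synthesize_eeg <- function(session, template = erp_template(session$group_profile),
                           montage = spherical_montage(), noise_rms = 10,
                           blink_rate = 0.03, fs = 1024, seed = 1L,
                           model = sphere_model(), duration_s = NULL,
                           subject_gain = 1) {
  if (!identical(template$group_profile, session$group_profile))
    stop_cfg("template profile '%s' does not match session profile '%s'",
             template$group_profile, session$group_profile)
  onsets <- session$trials$feedback_onset
  t_end <- max(onsets) + 1.5
  if (is.null(duration_s)) duration_s <- t_end + 0.5
  if (t_end > duration_s)
    stop_cfg("duration error: session extends to %.1f s, beyond the %.1f s recording",
             t_end, duration_s)
  n_samp <- ceiling(duration_s * fs)
  nch <- n_channels(montage)
  dirs <- montage$pos / sqrt(rowSums(montage$pos^2))
  topo <- dipole_potential(model, dirs, template$dipole_pos,
                           template$dipole_ori)
  # normalise so the mastoid-referenced Fz deflection equals the template
  # amplitude (the analysis-side reference convention)
  topo <- topo / (topo[montage$fz] - mean(topo[montage$mastoids]))
  with_seed(seed, {
    if (is.na(subject_gain))
      subject_gain <- exp(stats::rnorm(1, 0, template$subject_sd))
    data <- if (noise_rms > 0) noise_rms * pink_noise(n_samp, fs, nch)
            else matrix(0, nch, n_samp)
    # ERP responses
    wave_len <- round(0.8 * fs)
    t_wave <- seq_len(wave_len) / fs
    w <- template_waveform(template, t_wave)
    conds <- session$trials$condition
    keys <- if (!is.null(session$trials$gain_key)) session$trials$gain_key
            else conds
    for (i in seq_along(onsets)) {
      g <- template$gains[[keys[i]]]
      if (is.null(g)) g <- 0
      s0 <- round(onsets[i] * fs) + 1L
      idx <- s0:(min(s0 + wave_len - 1L, n_samp))
      amp <- template$base_amplitude_uv * g * subject_gain
      data[, idx] <- data[, idx] +
        outer(topo, amp * w[seq_along(idx)])
    }
    # blink artifacts: frontal-weighted low-frequency transients
    if (blink_rate > 0) {
      nb <- stats::rpois(1, blink_rate * duration_s)
      if (nb > 0) {
        bw_len <- round(0.3 * fs)
        bw <- sin(pi * seq_len(bw_len) / bw_len)^2
        front <- pmax(0, dirs[, 2] + 0.6 * dirs[, 3])^2
        front <- front / max(front)
        for (b in seq_len(nb)) {
          s0 <- sample.int(n_samp - bw_len, 1)
          idx <- s0:(s0 + bw_len - 1L)
          data[, idx] <- data[, idx] + outer(front, 250 * bw)
        }
      }
    }
    events <- data.frame(
      sample = round(onsets * fs) + 1L, onset_s = onsets,
      trial_index = session$trials$index, condition = conds,
      usable = session$trials$usable, stringsAsFactors = FALSE)
    out <- list(data = data, fs = fs, montage = montage, events = events,
                session = list(participant_id = session$participant_id,
                               group_profile = session$group_profile,
                               paradigm = session$paradigm),
                seed = seed, subject_gain = subject_gain,
                noise_rms = noise_rms)
    class(out) <- "eeg_continuous"
    out
  })
}

#' @export
print.eeg_continuous <- function(x, ...) {
  cat(sprintf("<eeg_continuous> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$events)))
  invisible(x)
}
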