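#' Preprocessing configuration
#'
#' Defaults reproduce the standard feedback-ERP chain: downsample to 256 Hz,
#' zero-phase 0.5-20 Hz bandpass, re-reference to averaged mastoids, epoch
#' -200..800 ms around feedback onset, baseline-correct on -200..0 ms, and
#' reject epochs by peak-to-peak and sample-to-sample gradient thresholds.
#'
#' @param target_fs downsampled rate in Hz (default 256).
#' @param band bandpass corner frequencies in Hz (default `c(0.5, 20)`).
#' @param epoch_window epoch window in ms relative to feedback onset,
#'   half-open `[lo, hi)` (default `c(-200, 800)`).
#' @param baseline_window baseline window in ms (default `c(-200, 0)`).
#' @param reject_ptp peak-to-peak rejection threshold in microvolts
#'   (default 150).
#' @param reject_grad max sample-to-sample step threshold in microvolts
#'   (default 75).
#' @return list of class `preproc_config`.
#' @export
preproc_config <- function(target_fs = 256, band = c(0.5, 20),
                           epoch_window = c(-200, 800),
                           baseline_window = c(-200, 0),
                           reject_ptp = 150, reject_grad = 75) {
  cfg <- list(target_fs = target_fs, band = band,
              epoch_window = epoch_window,
              baseline_window = baseline_window,
              reject_ptp = reject_ptp, reject_grad = reject_grad)
  class(cfg) <- "preproc_config"
  validate_preproc_config(cfg)
  cfg
}

# Zero-phase filtering of a channels x samples matrix: the forward-backward
# (filtfilt) response |H(w)|^2 of one or more IIR sections is applied in the
# frequency domain after reflection padding, one FFT over all channels.
zerophase_filter <- function(mat, filters, fs) {
  n <- ncol(mat)
  pad <- min(n - 1L, round(4 * fs))
  N <- stats::nextn(n + 2L * pad, c(2, 3, 5))   # FFT-friendly length
  padded <- cbind(mat[, pad:1, drop = FALSE], mat,
                  mat[, n:(n - pad + 1L), drop = FALSE],
                  matrix(0, nrow(mat), N - n - 2L * pad))
  w <- 2 * pi * (seq_len(N) - 1L) / N
  z <- exp(-1i * w)
  horner <- function(coef, z) {
    r <- rep(0 + 0i, length(z))
    for (c in rev(coef)) r <- r * z + c
    r
  }
  gain <- rep(1, N)
  for (f in filters)
    gain <- gain * Mod(horner(f$b, z) / horner(f$a, z))^2
  X <- stats::mvfft(t(padded))
  out <- Re(stats::mvfft(X * gain, inverse = TRUE)) / N
  t(out)[, pad + seq_len(n), drop = FALSE]
}

validate_preproc_config <- function(cfg) {
  if (cfg$band[1] <= 0 || cfg$band[1] >= cfg$band[2] ||
      cfg$band[2] >= cfg$target_fs / 2)
    stop_cfg("configuration error: need 0 < band low < band high < target_fs/2")
  w <- cfg$epoch_window; b <- cfg$baseline_window
  if (w[1] >= w[2] || w[1] > 0 || w[2] < 0)
    stop_cfg("configuration error: epoch window must contain 0 (got %g..%g ms)",
             w[1], w[2])
  if (b[1] < w[1] || b[2] > w[2] || b[1] >= b[2])
    stop_cfg("configuration error: baseline window must lie inside the epoch window")
  if (cfg$reject_ptp <= 0 || cfg$reject_grad <= 0)
    stop_cfg("configuration error: rejection thresholds must be positive")
  invisible(cfg)
}

#' Downsample continuous EEG with anti-alias filtering
#'
#' Integer-factor decimation after a zero-phase anti-alias low-pass at
#' 0.4 x `target_fs`. Event sample indices are remapped to the new rate
#' (error at most one output sample).
#'
#' @param raw an `eeg_continuous`.
#' @param target_fs target rate; must divide `raw$fs`.
#' @return the downsampled `eeg_continuous`.
#' @export
downsample <- function(raw, target_fs = 256) {
  if (target_fs > raw$fs) stop_cfg("target_fs (%g) exceeds sampling rate (%g)",
                                   target_fs, raw$fs)
  if (raw$fs %% target_fs != 0)
    stop_cfg("target_fs must divide the sampling rate (%g / %g)",
             raw$fs, target_fs)
  k <- raw$fs %/% target_fs
  if (k == 1L) return(raw)
  bf <- signal::butter(6, (0.4 * target_fs) / (raw$fs / 2), type = "low")
  n <- ncol(raw$data)
  keep <- seq(1L, n, by = k)
  out <- raw
  filtered <- zerophase_filter(raw$data, list(bf), raw$fs)
  out$data <- filtered[, keep, drop = FALSE]
  out$fs <- target_fs
  out$events$sample <- pmin(length(keep),
                            floor((raw$events$sample - 1L) / k) + 1L)
  out
}

#' Zero-phase bandpass filter
#'
#' 4th-order Butterworth high-pass and low-pass sections applied
#' forward-backward (`signal::filtfilt`), so component latencies are not
#' shifted.
#'
#' @param raw an `eeg_continuous`.
#' @param low,high corner frequencies in Hz.
#' @return the filtered `eeg_continuous`.
#' @export
bandpass <- function(raw, low = 0.5, high = 20) {
  if (low <= 0 || low >= high || high >= raw$fs / 2)
    stop_cfg("invalid band: need 0 < %g < %g < fs/2 = %g", low, high, raw$fs / 2)
  hp <- signal::butter(4, low / (raw$fs / 2), type = "high")
  lp <- signal::butter(4, high / (raw$fs / 2), type = "low")
  out <- raw
  out$data <- zerophase_filter(raw$data, list(hp, lp), raw$fs)
  out
}

#' Re-reference to averaged mastoids
#'
#' Subtracts the instantaneous mean of the two mastoid channels from every
#' channel; afterwards the mean of the two re-referenced mastoids is zero at
#' every sample, and the result is invariant to any common offset of the
#' input channels.
#'
#' @param raw an `eeg_continuous` whose montage names both mastoids.
#' @return the re-referenced `eeg_continuous`.
#' @export
rereference_mastoids <- function(raw) {
  mi <- raw$montage$mastoids
  if (is.null(mi) || length(mi) != 2L)
    stop_cfg("montage does not identify a mastoid pair")
  ref <- colMeans(raw$data[mi, , drop = FALSE])
  out <- raw
  out$data <- raw$data - matrix(ref, nrow(raw$data), ncol(raw$data),
                                byrow = TRUE)
  out$reference <- "averaged mastoids"
  out
}

#' Extract feedback-locked epochs
#'
#' Cuts one epoch per usable feedback event (for the observed social task
#' only correctly answered trials are usable) on the half-open window
#' `[lo, hi)` ms, so a -200..800 ms window at 256 Hz yields exactly 256
#' samples with the time axis starting at -200 ms inclusive. Events whose
#' window would exceed the recording are skipped with reason `"boundary"`.
#'
#' @param raw an `eeg_continuous`.
#' @param window epoch window in ms (default `c(-200, 800)`).
#' @return object of class `eeg_epochs`: `data` (epochs x channels x time,
#'   microvolts), `time_ms`, `labels`, `montage`, `fs`, rejection bookkeeping
#'   and a `skipped` log.
#' @export
extract_epochs <- function(raw, window = c(-200, 800)) {
  ev <- raw$events[raw$events$usable, , drop = FALSE]
  if (nrow(ev) == 0L) stop_cfg("no usable events to epoch")
  if (window[1] >= window[2] || window[1] > 0 || window[2] < 0)
    stop_cfg("invalid epoch window")
  fs <- raw$fs
  i0 <- round(window[1] / 1000 * fs)          # inclusive offset
  i1 <- round(window[2] / 1000 * fs) - 1L     # half-open upper end
  n_t <- i1 - i0 + 1L
  nch <- nrow(raw$data)
  ok <- ev$sample + i0 >= 1L & ev$sample + i1 <= ncol(raw$data)
  skipped <- if (any(!ok))
    data.frame(trial_index = ev$trial_index[!ok], reason = "boundary")
  else data.frame(trial_index = integer(0), reason = character(0))
  ev <- ev[ok, , drop = FALSE]
  if (nrow(ev) == 0L) stop_cfg("all events fall outside the recording")
  data <- array(0, dim = c(nrow(ev), nch, n_t))
  for (i in seq_len(nrow(ev)))
    data[i, , ] <- raw$data[, (ev$sample[i] + i0):(ev$sample[i] + i1)]
  out <- list(data = data, time_ms = (i0:i1) / fs * 1000, fs = fs,
              labels = ev$condition, trial_index = ev$trial_index,
              montage = raw$montage, baseline_applied = FALSE,
              rejected = rep(FALSE, nrow(ev)),
              reject_reason = rep(NA_character_, nrow(ev)),
              skipped = skipped)
  class(out) <- "eeg_epochs"
  out
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples (%.0f..%.0f ms @ %g Hz)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$time_ms), max(x$time_ms), x$fs))
  cat(sprintf("  baseline applied: %s; rejected: %d\n",
              x$baseline_applied, sum(x$rejected)))
  print(table(x$labels))
  invisible(x)
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the baseline window.
#' Refuses double application.
#'
#' @param epochs an `eeg_epochs`.
#' @param window baseline window in ms (default `c(-200, 0)`).
#' @return the corrected `eeg_epochs` with `baseline_applied = TRUE`.
#' @export
baseline_correct <- function(epochs, window = c(-200, 0)) {
  if (isTRUE(epochs$baseline_applied))
    stop_cfg("baseline correction already applied")
  sel <- epochs$time_ms >= window[1] & epochs$time_ms < window[2]
  if (!any(sel)) stop_cfg("baseline window contains no samples")
  bl <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl)  # recycles over time (3rd dim)
  epochs$baseline_applied <- TRUE
  epochs$baseline_window <- window
  epochs
}

#' Threshold-based artifact rejection
#'
#' Flags an epoch as rejected if, on any channel, the peak-to-peak amplitude
#' exceeds `ptp` or the maximum absolute sample-to-sample step exceeds
#' `grad`. A deterministic stand-in for the usual semi-automated screening;
#' `override` forces specific trials in or out by index.
#'
#' @param epochs an `eeg_epochs`.
#' @param ptp peak-to-peak threshold in microvolts.
#' @param grad gradient threshold in microvolts per sample.
#' @param override optional named logical vector (names = trial indices):
#'   manual keep/reject decisions applied after thresholding.
#' @return the `eeg_epochs` with the rejection mask and per-condition
#'   retention counts in `$retention`.
#' @export
reject_artifacts <- function(epochs, ptp = 150, grad = 75, override = NULL) {
  if (ptp <= 0 || grad <= 0) stop_cfg("rejection thresholds must be positive")
  n <- dim(epochs$data)[1]
  rej <- logical(n); reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    x <- epochs$data[i, , , drop = TRUE]
    ptps <- apply(x, 1, function(v) diff(range(v)))
    grads <- apply(x, 1, function(v) max(abs(diff(v))))
    if (max(ptps) > ptp) { rej[i] <- TRUE; reason[i] <- "peak-to-peak" }
    else if (max(grads) > grad) { rej[i] <- TRUE; reason[i] <- "gradient" }
  }
  if (!is.null(override)) {
    ix <- match(as.integer(names(override)), epochs$trial_index)
    ok <- !is.na(ix)
    rej[ix[ok]] <- override[ok]
    reason[ix[ok]] <- ifelse(override[ok], "manual", NA_character_)
  }
  epochs$rejected <- rej
  epochs$reject_reason <- reason
  epochs$retention <- as.data.frame(table(
    condition = epochs$labels, retained = !rej), stringsAsFactors = FALSE)
  if (all(rej)) warning("all epochs rejected", call. = FALSE)
  epochs
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper: downsample, bandpass, mastoid re-reference, epoch,
#' baseline-correct, reject artifacts, in the standard order.
#'
#' @param raw an `eeg_continuous`.
#' @param cfg a [preproc_config()].
#' @return an `eeg_epochs` ready for condition averaging.
#' @export
preprocess_eeg <- function(raw, cfg = preproc_config()) {
  validate_preproc_config(cfg)
  raw <- downsample(raw, cfg$target_fs)
  raw <- bandpass(raw, cfg$band[1], cfg$band[2])
  raw <- rereference_mastoids(raw)
  ep <- extract_epochs(raw, cfg$epoch_window)
  ep <- baseline_correct(ep, cfg$baseline_window)
  reject_artifacts(ep, cfg$reject_ptp, cfg$reject_grad)
}
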