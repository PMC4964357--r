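#' Analysis configuration for fERN statistics
#'
#' @param electrode channel used for component quantification (default
#'   `"Fz"`).
#' @param fern_window component window in ms post-feedback, half-open
#'   (default `c(250, 400)`).
#' @param n_resamples Monte Carlo resamples for the bootstrap null
#'   (default 5000).
#' @param alpha significance level (default 0.05).
#' @param null_method `"bootstrap"` (resampling with replacement from the
#'   pooled sample, the default) or `"permutation"` (label shuffling,
#'   available for sensitivity analysis).
#' @param seed integer seed for the resampling.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(electrode = "Fz", fern_window = c(250, 400),
                            n_resamples = 5000, alpha = 0.05,
                            null_method = c("bootstrap", "permutation"),
                            seed = 1L) {
  null_method <- match.arg(null_method)
  if (fern_window[1] >= fern_window[2])
    stop_cfg("configuration error: fern window reversed")
  if (!is_count(n_resamples))
    stop_cfg("configuration error: n_resamples must be a positive integer")
  if (alpha <= 0 || alpha >= 1)
    stop_cfg("configuration error: alpha must lie in (0, 1)")
  cfg <- list(electrode = electrode, fern_window = fern_window,
              n_resamples = n_resamples, alpha = alpha,
              null_method = null_method, seed = seed)
  class(cfg) <- "analysis_config"
  cfg
}

#' Average surviving epochs of one condition
#'
#' Pointwise mean over non-rejected epochs carrying the given label (or any
#' of several labels, each averaged first and the option means then averaged
#' — the subject-wise two-options-per-condition scheme).
#'
#' @param epochs an `eeg_epochs`.
#' @param label condition label, or character vector of option labels pooled
#'   into one condition.
#' @return object of class `fern_erp`: `waveform` (channels x time,
#'   microvolts), `time_ms`, `n_epochs`, `label`, `montage`, `options`.
#' @export
average_condition <- function(epochs, label) {
  keep <- !epochs$rejected
  per_option <- lapply(label, function(l) {
    sel <- keep & epochs$labels == l
    if (!any(sel)) return(NULL)   # empty option: drop from the pooled mean
    list(mean = apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean),
         n = sum(sel))
  })
  per_option <- Filter(Negate(is.null), per_option)
  if (length(per_option) == 0L)
    stop_cfg("no surviving epochs for condition '%s'",
             paste(label, collapse = "+"))
  wf <- Reduce(`+`, lapply(per_option, `[[`, "mean")) / length(per_option)
  out <- list(waveform = wf, time_ms = epochs$time_ms, fs = epochs$fs,
              n_epochs = sum(vapply(per_option, `[[`, 0L, "n")),
              label = paste(label, collapse = "+"), options = label,
              montage = epochs$montage)
  class(out) <- "fern_erp"
  out
}

#' @export
print.fern_erp <- function(x, ...) {
  cat(sprintf("<fern_erp> '%s': %d channels x %d samples, %d epochs\n",
              x$label, nrow(x$waveform), ncol(x$waveform), x$n_epochs))
  invisible(x)
}

#' @export
plot.fern_erp <- function(x, channel = "Fz", ...) {
  i <- channel_index(x$montage, channel)
  graphics::plot(x$time_ms, x$waveform[i, ], type = "l",
                 xlab = "time (ms)", ylab = sprintf("%s (µV)", channel),
                 main = x$label, ...)
  graphics::abline(v = 0, lty = 3); graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Mean fERN amplitude
#'
#' Mean of the chosen electrode's waveform over the component window
#' (half-open, default 250-400 ms post-feedback), in microvolts.
#'
#' @param erp a `fern_erp`.
#' @param cfg an [analysis_config()].
#' @return scalar amplitude in microvolts.
#' @export
fern_amplitude <- function(erp, cfg = analysis_config()) {
  i <- channel_index(erp$montage, cfg$electrode)
  sel <- erp$time_ms >= cfg$fern_window[1] & erp$time_ms < cfg$fern_window[2]
  if (!any(sel))
    stop_cfg("fern window %g..%g ms outside the epoch", cfg$fern_window[1],
             cfg$fern_window[2])
  mean(erp$waveform[i, sel])
}

#' Cohen's d (pooled standard deviation)
#'
#' Standardised mean difference `(mean(a) - mean(b)) / s_pooled` with the
#' n-1 pooled standard deviation. Undefined (NA with a message attribute)
#' when the pooled SD is zero.
#'
#' @param a,b numeric samples of size >= 2.
#' @return scalar effect size.
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop_cfg("both samples must have at least 2 observations")
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) return(structure(NA_real_, reason = "zero pooled SD"))
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Per-channel condition-difference topography
#'
#' Channel-wise `A - B` at one timepoint (typically the time of maximal
#' condition difference), for scalp maps of the component contrast.
#'
#' @param erpA,erpB `fern_erp` objects on a shared montage and time axis.
#' @param t_ms requested timepoint in ms (nearest sample used).
#' @return named numeric vector, one value per channel (microvolts).
#' @export
difference_topography <- function(erpA, erpB, t_ms) {
  if (!identical(erpA$montage$names, erpB$montage$names) ||
      !isTRUE(all.equal(erpA$time_ms, erpB$time_ms)))
    stop_cfg("ERPs must share montage and time axis")
  if (t_ms < min(erpA$time_ms) || t_ms > max(erpA$time_ms))
    stop_cfg("timepoint %g ms outside the epoch", t_ms)
  i <- which.min(abs(erpA$time_ms - t_ms))
  stats::setNames(erpA$waveform[, i] - erpB$waveform[, i],
                  erpA$montage$names)
}

#' Demographic covariate checks
#'
#' Within-group Spearman rank correlation between age and an EEG measure
#' (fERN amplitude or ROI activation), and a gender contrast via the
#' Mann-Whitney test. A constant measure yields an explicit
#' "undefined" flag rather than a correlation.
#'
#' @param measure numeric per-subject EEG measure.
#' @param age numeric ages (years).
#' @param gender factor/character with two levels.
#' @return list with `age_correlation` (rho, p or undefined flag) and
#'   `gender_contrast` (a `group_comparison`, or an undefined flag when a
#'   gender level has fewer than 2 subjects).
#' @export
covariate_checks <- function(measure, age, gender = NULL) {
  stopifnot(length(measure) == length(age))
  if (length(measure) < 3L)
    stop_cfg("need at least 3 subjects for the age correlation")
  age_res <- if (stats::sd(measure) == 0 || stats::sd(age) == 0) {
    list(undefined = TRUE, reason = "constant measure or age")
  } else {
    ct <- suppressWarnings(stats::cor.test(measure, age, method = "spearman"))
    list(undefined = FALSE, rho = unname(ct$estimate), p = ct$p.value)
  }
  gender_res <- NULL
  if (!is.null(gender)) {
    g <- split(measure, gender)
    gender_res <- if (length(g) == 2L && all(lengths(g) >= 2L))
      mannwhitney_groups(g[[1]], g[[2]])
    else list(undefined = TRUE, reason = "fewer than 2 subjects in a gender level")
  }
  list(age_correlation = age_res, gender_contrast = gender_res)
}
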