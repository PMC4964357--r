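#' Bootstrap Monte Carlo test of a waveform condition difference
#'
#' Pointwise two-sample comparison of two sets of waveforms inside the
#' component window. The observed pooled-variance t statistic is computed at
#' every timepoint; the null distribution is built by drawing, `n_resamples`
#' times, a resample *with replacement* from the pooled data, splitting it
#' into the original group sizes and recomputing the t statistic (a
#' bootstrap null; a label-permutation null is available via the config).
#' The two-sided Monte Carlo p value uses the add-one convention
#' `(1 + #(|t*| >= |t_obs|)) / (1 + B)`, so it is never exactly zero.
#'
#' Reported quantities follow standard practice for this design: the
#' temporal extents of pointwise significance inside the window (no
#' correction across timepoints), the t, p and Cohen's d at the timepoint of
#' maximal absolute condition difference, and additionally a familywise
#' omnibus p based on the null distribution of the window-wide maximum
#' absolute t (used for cohort-level detection decisions).
#'
#' Rows are the sampling units: trials for a within-subject contrast, or
#' subject-level condition means for a group-level contrast.
#'
#' @param a,b numeric matrices (units x time) on a common time axis, e.g.
#'   single-electrode trial data or per-subject condition waveforms.
#' @param time_ms time axis in ms matching the columns of `a` and `b`.
#' @param cfg an [analysis_config()]; supplies the component window, number
#'   of resamples, alpha, null method and seed.
#' @return object of class `fern_test`: `time_ms` (window timepoints),
#'   `t_obs`, `p` (pointwise), `mask`, `extents_ms`, `max_diff` (time, t, p,
#'   d, mean difference), `p_omnibus`, `n` (group sizes), and resampling
#'   metadata.
#' @examples
#' set.seed(1)
#' a <- matrix(rnorm(20 * 10), 20)          # null data
#' b <- matrix(rnorm(20 * 10), 20)
#' r <- montecarlo_bootstrap_test(a, b, time_ms = seq(250, 385, 15),
#'        cfg = analysis_config(n_resamples = 500))
#' r$p_omnibus > 0.05
#' @export
montecarlo_bootstrap_test <- function(a, b, time_ms,
                                      cfg = analysis_config()) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b) || ncol(a) != length(time_ms))
    stop_cfg("groups must share the time axis")
  if (nrow(a) < 2L || nrow(b) < 2L)
    stop_cfg("both conditions need at least 2 units")
  B <- cfg$n_resamples
  if (B < 100) warning("fewer than 100 resamples: Monte Carlo p is coarse",
                       call. = FALSE)
  sel <- time_ms >= cfg$fern_window[1] & time_ms < cfg$fern_window[2]
  if (!any(sel)) stop_cfg("component window %g..%g ms contains no timepoints",
                          cfg$fern_window[1], cfg$fern_window[2])
  tw <- time_ms[sel]
  P <- rbind(a[, sel, drop = FALSE], b[, sel, drop = FALSE])
  nA <- nrow(a); nB <- nrow(b); n <- nA + nB
  t_obs <- pooled_t(colMeans(P[seq_len(nA), , drop = FALSE]),
                    colMeans(P[nA + seq_len(nB), , drop = FALSE]),
                    apply(P[seq_len(nA), , drop = FALSE], 2, stats::var),
                    apply(P[nA + seq_len(nB), , drop = FALSE], 2, stats::var),
                    nA, nB)
  null_t <- with_seed(cfg$seed, {
    CA <- matrix(0L, n, B); CB <- matrix(0L, n, B)
    for (bb in seq_len(B)) {
      idx <- sample.int(n, n, replace = cfg$null_method == "bootstrap")
      CA[, bb] <- tabulate(idx[seq_len(nA)], n)
      CB[, bb] <- tabulate(idx[nA + seq_len(nB)], n)
    }
    sA <- crossprod(P, CA); sB <- crossprod(P, CB)         # T x B sums
    qA <- crossprod(P^2, CA); qB <- crossprod(P^2, CB)     # sums of squares
    mA <- sA / nA; mB <- sB / nB
    vA <- (qA - nA * mA^2) / (nA - 1)
    vB <- (qB - nB * mB^2) / (nB - 1)
    pooled_t(mA, mB, vA, vB, nA, nB)
  })
  abs_obs <- abs(t_obs)
  p <- (1 + rowSums(abs(null_t) >= abs_obs)) / (1 + B)
  mask <- p < cfg$alpha
  diff_obs <- colMeans(a[, sel, drop = FALSE]) -
    colMeans(b[, sel, drop = FALSE])
  i_max <- which.max(abs(diff_obs))
  max_null <- apply(abs(null_t), 2, max)
  p_omni <- (1 + sum(max_null >= max(abs_obs))) / (1 + B)
  out <- list(time_ms = tw, t_obs = t_obs, p = p, mask = mask,
              extents_ms = mask_extents(mask, tw),
              max_diff = list(time_ms = tw[i_max], t = t_obs[i_max],
                              p = p[i_max],
                              d = cohens_d(a[, sel, drop = FALSE][, i_max],
                                           b[, sel, drop = FALSE][, i_max]),
                              difference = diff_obs[i_max]),
              p_omnibus = p_omni, n = c(nA, nB),
              n_resamples = B, null_method = cfg$null_method,
              alpha = cfg$alpha, seed = cfg$seed)
  class(out) <- "fern_test"
  out
}

# Pooled-variance two-sample t; degenerate (zero pooled variance) -> 0.
pooled_t <- function(mA, mB, vA, vB, nA, nB) {
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  se <- sqrt(pmax(sp2, 0) * (1 / nA + 1 / nB))
  out <- (mA - mB) / se
  out[!is.finite(out)] <- 0
  out
}

# Runs of TRUE in the mask -> list of ms intervals (start, end inclusive).
mask_extents <- function(mask, time_ms) {
  if (!any(mask)) return(matrix(numeric(0), 0, 2,
                                dimnames = list(NULL, c("start", "end"))))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = time_ms[starts[keep]], end = time_ms[ends[keep]])
}

#' @export
print.fern_test <- function(x, ...) {
  cat(sprintf("<fern_test> %s null, %d resamples, n = %d/%d\n",
              x$null_method, x$n_resamples, x$n[1], x$n[2]))
  md <- x$max_diff
  cat(sprintf("  max difference at %.0f ms: t = %.2f, p = %.4f, d = %.2f\n",
              md$time_ms, md$t, md$p, md$d))
  cat(sprintf("  omnibus (max-|t|) p = %.4f\n", x$p_omnibus))
  if (nrow(x$extents_ms) == 0L) {
    cat(sprintf("  no pointwise significance at alpha = %g\n", x$alpha))
  } else {
    cat(sprintf("  significant extents (pointwise, alpha = %g): %s ms\n",
                x$alpha,
                paste(apply(round(x$extents_ms), 1, paste, collapse = "-"),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.fern_test <- function(object, ...) {
  print(object)
  cat("\nPointwise results:\n")
  print(data.frame(time_ms = round(object$time_ms, 1),
                   t = round(object$t_obs, 3), p = round(object$p, 4),
                   significant = object$mask), row.names = FALSE)
  invisible(object)
}

#' @export
plot.fern_test <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time_ms, x$t_obs, type = "l", xlab = "", ylab = "t")
  if (nrow(x$extents_ms) > 0)
    for (i in seq_len(nrow(x$extents_ms)))
      graphics::rect(x$extents_ms[i, 1], graphics::par("usr")[3],
                     x$extents_ms[i, 2], graphics::par("usr")[4],
                     col = grDevices::adjustcolor("red", 0.15), border = NA)
  graphics::plot(x$time_ms, x$p, type = "l", xlab = "time (ms)", ylab = "p",
                 ylim = c(0, 1))
  graphics::abline(h = x$alpha, lty = 2)
  invisible(x)
}

#' Trial-level electrode data for one condition
#'
#' Extracts the surviving single-trial waveforms of one condition at one
#' electrode, as a units x time matrix suitable for
#' [montecarlo_bootstrap_test()].
#'
#' @param epochs an `eeg_epochs`.
#' @param label condition label(s) pooled together.
#' @param electrode channel name (default "Fz").
#' @return numeric matrix (trials x time) with the epoch time axis as
#'   attribute `time_ms`.
#' @export
condition_trials <- function(epochs, label, electrode = "Fz") {
  i <- channel_index(epochs$montage, electrode)
  sel <- !epochs$rejected & epochs$labels %in% label
  if (!any(sel)) stop_cfg("no surviving epochs for condition '%s'",
                          paste(label, collapse = "+"))
  m <- epochs$data[sel, i, , drop = FALSE]
  structure(matrix(m, nrow = sum(sel)), time_ms = epochs$time_ms)
}
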