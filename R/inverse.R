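#' Inverse-solution configuration
#'
#' @param depth_exponent depth-weighting exponent gamma: source-covariance
#'   weights are `||g_i||^(-2 * gamma)` (default 0.8; 0 disables depth
#'   weighting).
#' @param snr assumed amplitude SNR setting the Tikhonov regularization,
#'   `lambda = trace(G W G') / (n_channels * snr^2)` (default 3).
#' @param noise_cov `"identity"` or `"baseline"`; with `"baseline"` the
#'   sample covariance of the baseline interval is shrunk towards identity.
#' @param shrinkage shrinkage weight towards identity for the baseline
#'   covariance (default 0.1).
#' @return list of class `inverse_config`.
#' @export
inverse_config <- function(depth_exponent = 0.8, snr = 3,
                           noise_cov = c("identity", "baseline"),
                           shrinkage = 0.1) {
  noise_cov <- match.arg(noise_cov)
  if (depth_exponent < 0) stop_cfg("configuration error: depth exponent must be >= 0")
  if (snr <= 0) stop_cfg("configuration error: SNR must be positive")
  cfg <- list(depth_exponent = depth_exponent, snr = snr,
              noise_cov = noise_cov, shrinkage = shrinkage)
  class(cfg) <- "inverse_config"
  cfg
}

# Inverse operator M (sources x channels) for a leadfield and config.
inverse_operator <- function(lead, cfg = inverse_config(), C = NULL) {
  G <- unclass(lead)
  nch <- nrow(G)
  w <- colSums(G^2)^(-cfg$depth_exponent)
  w <- w / mean(w)
  K <- G %*% (w * t(G))                 # G W G'
  if (is.null(C)) C <- diag(nch)
  C <- C * nch / sum(diag(C))           # unit average variance
  lambda <- sum(diag(K)) / (nch * cfg$snr^2)
  A <- K + lambda * C
  Ai <- tryCatch(solve(A), error = function(e)
    stop_cfg("numerical error inverting regularized gram matrix (lambda = %.3g): %s",
             lambda, conditionMessage(e)))
  list(M = (w * t(G)) %*% Ai, lambda = lambda)
}

#' Depth-weighted L2 minimum-norm source estimate
#'
#' Linear inverse `J = W G' (G W G' + lambda C)^-1 Y` applied per timepoint,
#' with diagonal source-covariance weights `w_i = ||g_i||^(-2 gamma)`
#' counteracting the minimum-norm bias towards superficial sources, and
#' Tikhonov regularization parameterised by an assumed SNR. Orientations are
#' fixed by the source space, so the estimate is a signed scalar moment per
#' source and timepoint; it is linear in the input data.
#'
#' @param lead a [build_spherical_leadfield()] gain matrix.
#' @param data a `fern_erp`, or a channels x time matrix matching the
#'   leadfield's channels.
#' @param cfg an [inverse_config()].
#' @param baseline_cov optional channels x channels noise covariance (used
#'   when `cfg$noise_cov == "baseline"`).
#' @return object of class `source_estimate`: `J` (sources x time), the time
#'   axis when known, the source space, and config provenance (`lambda`).
#' @export
depth_weighted_min_norm <- function(lead, data, cfg = inverse_config(),
                                    baseline_cov = NULL) {
  space <- attr(lead, "space")
  time_ms <- NULL
  if (inherits(data, "fern_erp")) {
    time_ms <- data$time_ms
    Y <- data$waveform
  } else Y <- as.matrix(data)
  if (nrow(Y) != nrow(lead))
    stop_cfg("data has %d channels but the leadfield %d", nrow(Y), nrow(lead))
  C <- if (cfg$noise_cov == "baseline" && !is.null(baseline_cov)) {
    S <- baseline_cov * nrow(Y) / sum(diag(baseline_cov))
    (1 - cfg$shrinkage) * S + cfg$shrinkage * diag(nrow(Y))
  } else NULL
  op <- inverse_operator(lead, cfg, C)
  Y <- Y - matrix(colMeans(Y), nrow(Y), ncol(Y), byrow = TRUE)  # avg ref
  out <- list(J = op$M %*% Y, time_ms = time_ms, space = space,
              lambda = op$lambda, config = cfg)
  class(out) <- "source_estimate"
  out
}

#' @export
print.source_estimate <- function(x, ...) {
  cat(sprintf("<source_estimate> %d sources x %d timepoints (lambda = %.3g, gamma = %g)\n",
              nrow(x$J), ncol(x$J), x$lambda, x$config$depth_exponent))
  invisible(x)
}

#' Condition-difference source map
#'
#' Per-source mean over the component window of the difference between two
#' source estimates (e.g. loss minus win, betrayal minus cooperation).
#'
#' @param srcA,srcB `source_estimate`s on the same source space/time axis.
#' @param window ms window averaged over (default `c(250, 400)`).
#' @return numeric vector, one signed value per source.
#' @export
condition_difference_map <- function(srcA, srcB, window = c(250, 400)) {
  if (!identical(dim(srcA$J), dim(srcB$J)) ||
      !isTRUE(all.equal(srcA$space$pos, srcB$space$pos)))
    stop_cfg("source estimates are on different source spaces")
  tm <- srcA$time_ms
  if (is.null(tm)) stop_cfg("source estimates carry no time axis")
  sel <- tm >= window[1] & tm < window[2]
  if (!any(sel)) stop_cfg("window %g..%g ms outside the data", window[1], window[2])
  rowMeans(srcA$J[, sel, drop = FALSE] - srcB$J[, sel, drop = FALSE])
}

#' ROI scalar of a source estimate
#'
#' Mean over the ROI's sources and the time window of the (signed) source
#' activity — the per-subject number entering group contrasts.
#'
#' @param src a `source_estimate`.
#' @param roi ROI label (default `"ACC"`).
#' @param window ms window (default `c(250, 400)`); ignored when the
#'   estimate has a single timepoint and no axis.
#' @return scalar.
#' @export
roi_scalar <- function(src, roi = "ACC", window = c(250, 400)) {
  ix <- src$space$rois[[roi]]
  if (is.null(ix) || length(ix) == 0L) stop_cfg("ROI '%s' is empty or unknown", roi)
  if (is.null(src$time_ms)) return(mean(src$J[ix, , drop = FALSE]))
  sel <- src$time_ms >= window[1] & src$time_ms < window[2]
  if (!any(sel)) stop_cfg("window %g..%g ms outside the data", window[1], window[2])
  mean(src$J[ix, sel, drop = FALSE])
}

#' Mann-Whitney U contrast between two groups
#'
#' Two-sided rank-sum test on per-subject scalars: exact when the combined
#' sample is small (n <= 20) and tie-free, tie-corrected normal
#' approximation otherwise. The effect size is `r = |Z| / sqrt(n1 + n2)`
#' with Z from the tie-corrected normal approximation.
#'
#' @param a,b numeric vectors of per-subject values (each length >= 2).
#' @return object of class `group_comparison`: `U` (for group `a`), `p`,
#'   `z`, `r`, group sizes, and a degenerate flag when all values tie.
#' @examples
#' mannwhitney_groups(c(1, 2, 3), c(4, 5, 6))
#' @export
mannwhitney_groups <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop_cfg("each group needs at least 2 subjects")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  ranks <- rank(c(a, b))
  U <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(a, b))
  degenerate <- length(ties) == 1L
  # tie-corrected normal approximation for Z (used for r, and for p when
  # exactness is unavailable)
  mu <- n1 * n2 / 2
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (sig2 > 0) (U - mu) / sqrt(sig2) else 0
  p <- if (degenerate) 1 else {
    exact <- n <= 20 && !any(ties > 1)
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = !exact))
    wt$p.value
  }
  out <- list(U = U, p = p, z = z, r = abs(z) / sqrt(n),
              n = c(n1, n2), degenerate = degenerate)
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> U = %.1f (n = %d/%d), p = %.4f, r = %.2f%s\n",
              x$U, x$n[1], x$n[2], x$p, x$r,
              if (x$degenerate) " [degenerate: all values tied]" else ""))
  invisible(x)
}
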