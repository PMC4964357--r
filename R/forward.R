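#' Analytic concentric-sphere EEG head model
#'
#' Three concentric shells (brain, skull, scalp) with piecewise-constant
#' conductivity. The scalp potential of a current dipole inside the inner
#' sphere is computed from the spherical-harmonic series solution: for each
#' harmonic degree the radial boundary-value problem (continuity of potential
#' and of radial current at each interface, zero current through the outer
#' surface) is solved exactly, giving a per-degree transfer coefficient that
#' replaces the homogeneous-sphere factor.
#'
#' @param radii interface radii in metres, innermost first (inner skull,
#'   outer skull, scalp). Default `c(0.080, 0.085, 0.090)`.
#' @param conductivities conductivity of brain, skull and scalp compartments
#'   in S/m; default `0.33 * c(1, 1/80, 1)`.
#' @param n_terms series truncation degree (default 60).
#' @return list of class `sphere_model`.
#' @export
sphere_model <- function(radii = c(0.080, 0.085, 0.090),
                         conductivities = 0.33 * c(1, 1 / 80, 1),
                         n_terms = 60) {
  stopifnot(length(radii) == length(conductivities),
            all(diff(radii) > 0), all(conductivities > 0))
  out <- list(radii = radii, cond = conductivities, n_terms = n_terms,
              transfer = shell_transfer(radii, conductivities, n_terms))
  class(out) <- "sphere_model"
  out
}

# Per-degree transfer coefficients T_n: scalp-surface potential produced by
# a unit source expansion coefficient (free-dipole term D r^-(n+1)).
# Homogeneous sphere reference value: (2n+1)/n * R^-(n+1).
shell_transfer <- function(radii, cond, n_terms) {
  M <- length(radii)
  if (M == 1L) {  # homogeneous sphere, insulating exterior: closed form
    n <- seq_len(n_terms)
    return((2 * n + 1) / n * radii^(-(n + 1)))
  }
  R <- radii[M]
  radii <- radii / R   # solve in scaled radii (u <= 1) for conditioning
  vapply(seq_len(n_terms), function(n) {
    # unknowns: A_1, (A_k, B_k) for k = 2..M  -> 2M - 1
    nu <- 2L * M - 1L
    A <- matrix(0, nu, nu)
    rhs <- numeric(nu)
    aidx <- function(k) if (k == 1L) 1L else 2L * k - 2L  # A_k column
    bidx <- function(k) 2L * k - 1L                       # B_k column (k>=2)
    row <- 0L
    for (k in seq_len(M - 1L)) {            # interface at radii[k]
      r <- radii[k]
      # potential continuity: A_k r^n + B_k r^-(n+1) [+ D r^-(n+1) if k==1]
      row <- row + 1L
      A[row, aidx(k)] <- r^n
      if (k > 1L) A[row, bidx(k)] <- r^(-(n + 1)) else rhs[row] <- -r^(-(n + 1))
      A[row, aidx(k + 1L)] <- -r^n
      A[row, bidx(k + 1L)] <- -r^(-(n + 1))
      # radial current continuity
      row <- row + 1L
      A[row, aidx(k)] <- cond[k] * n * r^(n - 1)
      if (k > 1L) A[row, bidx(k)] <- -cond[k] * (n + 1) * r^(-(n + 2))
      else rhs[row] <- -cond[k] * (n + 1) * r^(-(n + 2)) * -1  # move D term
      A[row, aidx(k + 1L)] <- -cond[k + 1L] * n * r^(n - 1)
      A[row, bidx(k + 1L)] <- cond[k + 1L] * (n + 1) * r^(-(n + 2))
    }
    # outer surface: zero radial current
    row <- row + 1L
    rM <- radii[M]
    A[row, aidx(M)] <- n * rM^(n - 1)
    A[row, bidx(M)] <- -(n + 1) * rM^(-(n + 2))
    x <- solve(A, rhs)
    (x[aidx(M)] * rM^n + x[bidx(M)] * rM^(-(n + 1))) * R^(-(n + 1))
  }, numeric(1))
}

# Legendre P_n(x) and associated P_n^1(x) = sqrt(1-x^2) P_n'(x) (no
# Condon-Shortley phase) for n = 1..N, vectorised over x.
legendre_table <- function(x, N) {
  P <- matrix(0, length(x), N + 1L)
  P[, 1] <- 1; P[, 2] <- x
  if (N >= 2) for (n in 2:N)
    P[, n + 1L] <- ((2 * n - 1) * x * P[, n] - (n - 1) * P[, n - 1L]) / n
  s <- sqrt(pmax(0, 1 - x^2))
  P1 <- matrix(0, length(x), N)
  for (n in 1:N) {
    num <- n * (P[, n] - x * P[, n + 1L])     # = (1-x^2) P_n'(x)
    P1[, n] <- ifelse(s > 1e-12, num / s, 0)
  }
  list(P = P[, -1, drop = FALSE], P1 = P1)    # degree 1..N
}

# Scalp potential (volts) at unit-sphere sensor directions for one dipole.
# pos: dipole position (m, inside innermost shell); mom: dipole moment (A*m).
dipole_potential <- function(model, sensor_dirs, pos, mom) {
  b <- sqrt(sum(pos^2))
  if (b >= model$radii[1])
    stop_cfg("geometry error: source at radius %.4f m is not strictly inside the inner sphere (%.4f m)",
             b, model$radii[1])
  N <- model$n_terms
  if (b < 1e-9) {                     # central dipole: treat as radial frame
    rhat <- c(0, 0, 1)
  } else rhat <- pos / b
  m_r <- sum(mom * rhat)
  t_vec <- mom - m_r * rhat
  m_t <- sqrt(sum(t_vec^2))
  xhat <- if (m_t > 1e-15) t_vec / m_t else c(0, 0, 0)
  cosg <- as.vector(sensor_dirs %*% rhat)
  cosg <- pmin(1, pmax(-1, cosg))
  e_perp <- sensor_dirs - outer(cosg, rhat)
  pn <- sqrt(rowSums(e_perp^2))
  cosphi <- ifelse(pn > 1e-12, as.vector(e_perp %*% xhat) / pn, 0)
  leg <- legendre_table(cosg, N)
  n_seq <- seq_len(N)
  bpow <- b^(n_seq - 1)
  coef <- model$transfer * bpow
  rad <- leg$P %*% (coef * n_seq) * m_r
  tan <- (leg$P1 %*% coef) * (m_t * cosphi)
  as.vector(rad + tan) / (4 * pi * model$cond[1])
}

#' Cortical-proxy source space inside a spherical head model
#'
#' Builds a layered spherical source sheet: approximately equidistant points
#' on upper-hemispheric caps at several radii (a superficial convexity
#' sheet, a medial-wall-depth sheet, and a deep sheet standing in for
#' non-cortical structures), each with a radial (surface-normal proxy) unit
#' orientation. The "ACC" region of interest is defined geometrically as the
#' frontal-midline sector of the two cortical sheets: sources with radius in
#' `acc_radius_range` (default 0.04-0.07 m, i.e. cingulate depth up to the
#' medial convexity), anterior (`y > 0.005` m), near the midline
#' (`|x| < 0.02` m) and not below the axial plane.
#'
#' @param model a [sphere_model()].
#' @param radii radii of the source shells in metres (all strictly inside the
#'   inner skull). Defaults `c(0.035, 0.050, 0.065)`.
#' @param n_per_shell points per shell (default 250).
#' @param acc_radius_range radial bounds of the ACC sector in metres.
#' @return list of class `source_space`: `pos` (n x 3 m), `ori` (n x 3 unit,
#'   radial), `rois` (named list of index vectors, includes `ACC`).
#' @export
source_space <- function(model = sphere_model(),
                         radii = c(0.035, 0.050, 0.065),
                         n_per_shell = 250,
                         acc_radius_range = c(0.04, 0.07)) {
  if (any(radii >= model$radii[1]))
    stop_cfg("geometry error: source shells must lie strictly inside the inner sphere")
  pts <- lapply(radii, function(r) {
    k <- seq_len(n_per_shell) - 0.5
    z <- 1 - 1.15 * k / n_per_shell          # cap down to z/r = -0.15
    th <- acos(z)
    az <- (k * pi * (3 - sqrt(5))) %% (2 * pi)
    r * cbind(sin(th) * sin(az), sin(th) * cos(az), z)
  })
  pos <- do.call(rbind, pts)
  rr <- sqrt(rowSums(pos^2))
  ori <- pos / rr
  acc <- which(rr >= acc_radius_range[1] - 1e-9 &
                 rr <= acc_radius_range[2] + 1e-9 & pos[, 2] > 0.005 &
                 abs(pos[, 1]) < 0.02 & pos[, 3] > -1e-9)
  out <- list(pos = pos, ori = ori, radius = rr,
              rois = list(ACC = acc), model = model)
  class(out) <- "source_space"
  out
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("<source_space> %d sources (radii %s m), ACC ROI: %d sources\n",
              nrow(x$pos), paste(format(unique(round(x$radius, 3))),
                                 collapse = "/"),
              length(x$rois$ACC)))
  invisible(x)
}

#' Leadfield of an analytic spherical head model
#'
#' Gain matrix (channels x sources, volts at the scalp per A*m of dipole
#' moment) for orientation-constrained sources: column i is the referenced
#' scalp potential pattern of a unit dipole at source i along its fixed
#' (radial) orientation, computed from the multi-shell series solution.
#' Potentials are referenced to the sensor-mean (the reference is reapplied
#' consistently by the inverse and by re-referenced data).
#'
#' @param montage an [spherical_montage()]; sensors are radially projected
#'   onto the outer shell.
#' @param space a [source_space()].
#' @param model a [sphere_model()]; defaults to the one stored in `space`.
#' @return matrix of class `leadfield` with attributes `montage` and `space`.
#' @export
build_spherical_leadfield <- function(montage, space, model = space$model) {
  dirs <- montage$pos / sqrt(rowSums(montage$pos^2))
  G <- vapply(seq_len(nrow(space$pos)), function(i)
    dipole_potential(model, dirs, space$pos[i, ], space$ori[i, ]),
    numeric(nrow(dirs)))
  G <- G - matrix(colMeans(G), nrow(G), ncol(G), byrow = TRUE)
  rownames(G) <- montage$names
  structure(G, class = c("leadfield", "matrix"),
            montage = montage, space = space, model = model)
}
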