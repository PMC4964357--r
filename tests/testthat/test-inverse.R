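setup_inverse <- function(n_scalp = 64, n_per_shell = 150) {
  model <- sphere_model()
  mont <- spherical_montage(n_scalp)
  space <- source_space(model, n_per_shell = n_per_shell)
  list(model = model, mont = mont, space = space,
       lead = build_spherical_leadfield(mont, space))
}

test_that("the minimum-norm estimate is linear and zero-preserving", {
  sI <- setup_inverse(16, 60)
  Y <- matrix(0, 18, 5)
  est0 <- depth_weighted_min_norm(sI$lead, Y)
  expect_equal(max(abs(est0$J)), 0)
  set.seed(2)
  Y1 <- matrix(rnorm(18 * 5), 18)
  e1 <- depth_weighted_min_norm(sI$lead, Y1)
  e2 <- depth_weighted_min_norm(sI$lead, 2 * Y1)
  expect_equal(e2$J, 2 * e1$J, tolerance = 1e-10)
  expect_error(depth_weighted_min_norm(sI$lead, Y1[1:5, ]), "channels")
})

loc_metrics <- function(sI, truth, gamma, y = NULL, snr = 100) {
  if (is.null(y)) y <- unclass(sI$lead)[, truth, drop = FALSE]
  est <- depth_weighted_min_norm(sI$lead, y,
                                 inverse_config(depth_exponent = gamma,
                                                snr = snr))
  J <- abs(est$J[, 1])
  i_hat <- which.max(J)
  w <- J^2 / sum(J^2)
  c(peak = sqrt(sum((sI$space$pos[i_hat, ] - sI$space$pos[truth, ])^2)),
    centroid = sqrt(sum((colSums(sI$space$pos * w) -
                           sI$space$pos[truth, ])^2)))
}

test_that("a noiseless ACC source localizes within 25 mm and depth
           weighting reduces the superficial localization bias", {
  sI <- setup_inverse()
  acc <- sI$space$rois$ACC
  # weak regularization for noiseless probes (noise -> 0, lambda -> 0)
  for (truth in acc[c(1, 5, 9)]) {
    m8 <- loc_metrics(sI, truth, 0.8)
    expect_lte(m8[["peak"]], 0.025)
  }
  # depth bias: for a deep source, the mass centroid of the gamma = 0.8
  # estimate is strictly closer to the truth than the unweighted one,
  # and the peak is never farther
  deep_truth <- which(sI$space$radius <= 0.045)[3]
  m8 <- loc_metrics(sI, deep_truth, 0.8)
  m0 <- loc_metrics(sI, deep_truth, 0)
  expect_lt(m8[["centroid"]], m0[["centroid"]])
  expect_lte(m8[["peak"]], m0[["peak"]])
})

test_that("localization error shrinks as sensor noise shrinks", {
  sI <- setup_inverse()
  truth <- sI$space$rois$ACC[2]
  y <- unclass(sI$lead)[, truth, drop = FALSE]
  set.seed(7)
  noise <- rnorm(nrow(y)); noise <- noise / sqrt(sum(noise^2)) * sqrt(sum(y^2))
  errs <- vapply(c(0.5, 0.1, 0), function(rel)
    loc_metrics(sI, truth, 0.8, y = y + rel * noise)[["peak"]], numeric(1))
  expect_true(all(diff(errs) <= 0))
  expect_lte(errs[3], 0.025)
})

test_that("condition difference maps and ROI scalars behave as contracts", {
  sI <- setup_inverse(16, 60)
  tms <- seq(0, 500, by = 20)
  set.seed(5)
  Y <- matrix(rnorm(18 * length(tms)), 18)
  est <- depth_weighted_min_norm(sI$lead, Y)
  est$time_ms <- tms
  expect_equal(max(abs(condition_difference_map(est, est))), 0)
  expect_error(condition_difference_map(est, est, window = c(900, 990)),
               "outside")
  # uniform field -> ROI scalar equals the field value; zero field -> 0
  u <- est; u$J <- matrix(3.3, nrow(est$J), ncol(est$J))
  expect_equal(roi_scalar(u, "ACC", c(0, 500)), 3.3)
  z <- est; z$J <- 0 * est$J
  expect_equal(roi_scalar(z, "ACC", c(0, 500)), 0)
  expect_error(roi_scalar(est, "no-such-roi"), "empty or unknown")
})

test_that("an ACC-generated condition difference is recovered in the ROI", {
  sI <- setup_inverse()
  acc <- sI$space$rois$ACC
  # a mid-sector ACC source (closest to the midline on the 50 mm sheet)
  cand <- acc[abs(sI$space$radius[acc] - 0.05) < 1e-6]
  truth <- cand[which.min(abs(sI$space$pos[cand, 1]))]
  tms <- seq(250, 395, by = 10)
  wave <- sin(pi * seq_along(tms) / length(tms))
  # control-like: difference driven by one ACC source; ADHD-like: none
  y_ctrl <- unclass(sI$lead)[, truth, drop = FALSE] %*% matrix(wave, 1)
  est_c <- depth_weighted_min_norm(sI$lead, y_ctrl,
                                   inverse_config(snr = 100))
  est_c$time_ms <- tms
  dm <- condition_difference_map(est_c,
                                 { z <- est_c; z$J <- 0 * z$J; z },
                                 c(250, 400))
  expect_true(which.max(abs(dm)) %in% acc)
  r_ctrl <- roi_scalar(est_c, "ACC", c(250, 400))
  expect_gt(abs(r_ctrl), 0)
})

test_that("Mann-Whitney results match enumeration and identities", {
  # identical groups: U = n1 n2 / 2 midpoint, p near 1
  r_id <- mannwhitney_groups(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r_id$U, 8)
  expect_gt(r_id$p, 0.5)
  # fully separated groups reach an extreme U and the minimal exact p
  r_lo <- mannwhitney_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r_lo$U, 0)
  expect_equal(r_lo$p, 2 * choose(6, 3)^-1 * 1, tolerance = 1e-12)  # 0.1
  r_hi <- mannwhitney_groups(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r_hi$U, 9)
  # exact p equals brute-force enumeration of group assignments
  set.seed(31)
  for (sizes in list(c(3, 3), c(4, 5), c(6, 6))) {
    x <- sample(100, sum(sizes))    # tie-free
    a <- x[seq_len(sizes[1])]; b <- x[sizes[1] + seq_len(sizes[2])]
    got <- mannwhitney_groups(a, b)
    combos <- utils::combn(sum(sizes), sizes[1])
    ustat <- function(aa, bb) sum(outer(aa, bb, ">"))
    u_null <- apply(combos, 2, function(ix) ustat(x[ix], x[-ix]))
    u_obs <- ustat(a, b)
    mu <- prod(sizes) / 2
    p_exact <- mean(abs(u_null - mu) >= abs(u_obs - mu))
    expect_equal(got$p, p_exact, tolerance = 1e-12)
    expect_equal(got$U, u_obs)
    # U identity
    expect_equal(got$U + mannwhitney_groups(b, a)$U, prod(sizes))
  }
  # ties: tie-corrected normal approximation, r in [0, 1]
  r_tie <- mannwhitney_groups(c(1, 1, 2, 2, 3), c(2, 2, 3, 3, 4))
  expect_gte(r_tie$r, 0); expect_lte(r_tie$r, 1)
  # degenerate: everything tied
  r_deg <- mannwhitney_groups(c(2, 2), c(2, 2))
  expect_true(r_deg$degenerate)
  expect_equal(r_deg$p, 1)
  expect_error(mannwhitney_groups(1, c(1, 2)), "at least 2")
})

test_that("group separation in ROI scalars is recovered from sensor data", {
  # subject-level sensor maps: control subjects carry an ACC difference
  # signal, ADHD subjects none; both get sensor noise
  sI <- setup_inverse()
  acc <- sI$space$rois$ACC
  y0 <- unclass(sI$lead)[, acc[1], drop = FALSE]
  scal <- function(signal, seed) {
    set.seed(seed)
    noise <- rnorm(length(y0)); noise <- noise / sqrt(sum(noise^2))
    y <- signal * y0 + 0.3 * sqrt(sum(y0^2)) * noise
    est <- depth_weighted_min_norm(sI$lead, y)
    mean(est$J[acc, ])
  }
  rejections <- vapply(1:12, function(rep) {
    ctrl <- vapply(1:12, function(i) scal(1, rep * 100 + i), numeric(1))
    adhd <- vapply(1:12, function(i) scal(0, rep * 100 + 50 + i), numeric(1))
    mannwhitney_groups(ctrl, adhd)$p < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.8)
})
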