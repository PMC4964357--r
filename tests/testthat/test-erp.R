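make_epochs <- function(waves, labels, time_ms = seq(-199.2, 796.9, by = 1000 / 256),
                        montage = tiny_montage(4)) {
  n_t <- length(time_ms); nch <- length(montage$names)
  data <- array(0, dim = c(length(labels), nch, n_t))
  for (i in seq_along(labels))
    data[i, , ] <- matrix(waves[[i]], nch, n_t, byrow = TRUE)
  structure(list(data = data, time_ms = time_ms, fs = 256, labels = labels,
                 trial_index = seq_along(labels), montage = montage,
                 baseline_applied = TRUE,
                 rejected = rep(FALSE, length(labels)),
                 reject_reason = rep(NA_character_, length(labels))),
            class = "eeg_epochs")
}

test_that("condition averaging pools epochs and options correctly", {
  tms <- seq(-199.2, 796.9, by = 1000 / 256)
  w <- sin(tms / 100)
  ep <- make_epochs(list(w, w, -w, w * 0 + 1, w * 0 - 1),
                    c("a", "a", "b", "c", "c"))
  # two identical epochs -> the epoch itself
  expect_equal(average_condition(ep, "a")$waveform[1, ], w)
  # +1 and -1 epochs -> zero
  expect_equal(max(abs(average_condition(ep, "c")$waveform)), 0)
  # option pooling averages option means, not trials: {a (2 epochs), b}
  ab <- average_condition(ep, c("a", "b"))
  expect_equal(ab$waveform[1, ], (w + (-w)) / 2)
  expect_equal(ab$n_epochs, 3)
  # rejected epochs never enter averages
  ep$rejected[2] <- TRUE
  expect_equal(average_condition(ep, "a")$n_epochs, 1)
  expect_error(average_condition(ep, "zzz"), "no surviving epochs")
})

test_that("simulated control loss average is more negative than win at Fz", {
  ep <- noiseless_epochs("control")
  cfg <- analysis_config()
  loss <- average_condition(ep, grep("^loss", unique(ep$labels), value = TRUE))
  win <- average_condition(ep, grep("^win", unique(ep$labels), value = TRUE))
  expect_lt(fern_amplitude(loss, cfg), fern_amplitude(win, cfg))
})

test_that("fERN amplitude is the window mean at the chosen electrode", {
  tms <- seq(-199.2, 796.9, by = 1000 / 256)
  cfg <- analysis_config()
  ep <- make_epochs(list(rep(2.5, length(tms))), "a")
  erp <- average_condition(ep, "a")
  expect_equal(fern_amplitude(erp, cfg), 2.5)
  # zero waveform -> 0
  ep0 <- make_epochs(list(rep(0, length(tms))), "a")
  expect_equal(fern_amplitude(average_condition(ep0, "a"), cfg), 0)
  # half-period sinusoid centred on the window: mean = 2/pi * peak
  sel <- tms >= 250 & tms < 400
  w <- numeric(length(tms))
  w[sel] <- sin(pi * (tms[sel] - 250) / 150)
  erp2 <- average_condition(make_epochs(list(w), "a"), "a")
  expect_equal(fern_amplitude(erp2, cfg), 2 / pi, tolerance = 0.02)
  expect_error(fern_amplitude(erp, analysis_config(fern_window = c(900, 950))),
               "outside the epoch")
  expect_error(fern_amplitude(erp, analysis_config(electrode = "Cz")),
               "not present")
})

test_that("Cohen's d matches the pooled-SD definition", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  # hand computation: means 2 and 4, both variances 1, pooled SD 1
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2)
  # brute-force formula on random data
  set.seed(8)
  a <- rnorm(11); b <- rnorm(7, 1)
  sp <- sqrt((10 * var(a) + 6 * var(b)) / 16)
  expect_equal(cohens_d(a, b), (mean(a) - mean(b)) / sp)
  d0 <- cohens_d(c(1, 1, 1), c(1, 1, 1))
  expect_true(is.na(d0))
  expect_equal(attr(d0, "reason"), "zero pooled SD")
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
})

test_that("difference topography subtracts channel-wise at a timepoint", {
  ep <- noiseless_epochs("control")
  loss <- average_condition(ep, grep("^loss", unique(ep$labels), value = TRUE))
  win <- average_condition(ep, grep("^win", unique(ep$labels), value = TRUE))
  expect_equal(max(abs(difference_topography(loss, loss, 300))), 0)
  shifted <- win; shifted$waveform <- win$waveform + 1
  expect_equal(unname(difference_topography(shifted, win, 300)),
               rep(1, nrow(win$waveform)))
  # ACC-generated difference peaks frontal-midline: biggest |difference|
  # within 35 degrees of Fz's direction
  topo <- difference_topography(loss, win, 310)
  mont <- loss$montage
  dirs <- mont$pos / sqrt(rowSums(mont$pos^2))
  ang <- acos(pmin(1, dirs %*% dirs[mont$fz, ]))
  expect_lte(ang[which.max(abs(topo))], 35 * pi / 180)
  expect_error(difference_topography(loss, win, 5000), "outside the epoch")
})

test_that("covariate checks flag degenerate inputs and recover true links", {
  flat <- covariate_checks(rep(1, 10), rnorm(10, 11),
                           rep(c("M", "F"), 5))
  expect_true(flat$age_correlation$undefined)
  ages <- runif(12, 8, 15)
  ident <- covariate_checks(ages, ages)
  expect_equal(ident$age_correlation$rho, 1)
  # age-independent measures: correlation null respected across seeds
  ps <- vapply(1:20, function(i) {
    set.seed(i)
    covariate_checks(rnorm(15), runif(15, 8, 15))$age_correlation$p
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.85)
  expect_error(covariate_checks(1:2, 1:2), "at least 3")
})
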