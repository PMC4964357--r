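test_that("downsampling decimates by the rate ratio and remaps events", {
  mont <- tiny_montage(4)
  n <- 4096
  data <- matrix(rnorm(6 * n), 6)
  raw <- raw_from_matrix(data, 1024, mont,
                         events = data.frame(sample = c(1024L, 2049L),
                                             onset_s = c(1, 2),
                                             trial_index = 1:2,
                                             condition = "x", usable = TRUE))
  d <- downsample(raw, 256)
  expect_equal(d$fs, 256)
  expect_equal(ncol(d$data), n / 4)
  # event at input sample 1024 lands within one output sample of t = 1 s
  expect_lte(abs(d$events$sample[1] / 256 - 1), 1 / 256 + 1e-9)
  expect_lte(abs(d$events$sample[2] / 256 - 2), 1 / 256 + 1e-9)
  # constant signal survives unchanged
  rawc <- raw_from_matrix(matrix(3.7, 6, n), 1024, mont)
  dc <- downsample(rawc, 256)
  expect_equal(max(abs(dc$data - 3.7)), 0, tolerance = 1e-8)
  expect_error(downsample(raw, 2048), "exceeds")
  expect_error(downsample(raw, 300), "divide")
})

test_that("bandpass has the designed frequency response and zero phase", {
  mont <- tiny_montage(4)
  fs <- 256
  t <- seq(0, 24, by = 1 / fs)
  mid <- seq(2000, 4000)
  for (case in list(list(f = 10, lo = 0.95, hi = 1.05),
                    list(f = 50, lo = 0, hi = 0.05))) {
    sig <- sin(2 * pi * case$f * t)
    raw <- raw_from_matrix(matrix(rep(sig, 6), 6, byrow = TRUE), fs, mont)
    out <- bandpass(raw, 0.5, 20)
    amp <- max(abs(out$data[1, mid]))
    expect_gte(amp, case$lo)
    expect_lte(amp, case$hi)
  }
  # all-zero signal stays zero
  rawz <- raw_from_matrix(matrix(0, 6, 2048), fs, mont)
  expect_equal(max(abs(bandpass(rawz, 0.5, 20)$data)), 0)
  # zero phase: a 10 Hz passband sinusoid keeps its zero crossings
  sig <- sin(2 * pi * 10 * t)
  raw <- raw_from_matrix(matrix(rep(sig, 6), 6, byrow = TRUE), fs, mont)
  out <- bandpass(raw, 0.5, 20)
  lag <- which.max(ccf(out$data[1, mid], sig[mid], lag.max = 5,
                       plot = FALSE)$acf) - 6
  expect_equal(lag, 0)
  expect_error(bandpass(raw, 20, 0.5), "invalid band")
})

test_that("mastoid re-referencing is the exact algebraic identity", {
  mont <- tiny_montage(4)   # channels: Fz, E001..E003, M1, M2
  data <- matrix(rnorm(6 * 500), 6)
  raw <- raw_from_matrix(data, 256, mont)
  rr <- rereference_mastoids(raw)
  expect_equal(max(abs(colMeans(rr$data[mont$mastoids, ]))), 0,
               tolerance = 1e-12)
  # invariance to a common offset
  raw2 <- raw; raw2$data <- raw$data + 42
  expect_equal(rereference_mastoids(raw2)$data, rr$data, tolerance = 1e-12)
  # hand computation: channel 5, mastoids 1 and 3 -> 5 - mean(1,3) = 3
  raw3 <- raw; raw3$data <- matrix(c(5, 5, 5, 5, 1, 3), 6, 500)
  expect_equal(unique(rereference_mastoids(raw3)$data[1, ]), 3)
})

test_that("epoching uses the half-open window and skips boundary events", {
  mont <- tiny_montage(4)
  data <- matrix(rnorm(6 * 2000), 6)
  ev <- data.frame(sample = c(10L, 600L, 1200L), onset_s = c(10, 600, 1200) / 256,
                   trial_index = 1:3, condition = c("a", "b", "a"),
                   usable = TRUE)
  raw <- raw_from_matrix(data, 256, mont, ev)
  ep <- extract_epochs(raw, c(-200, 800))
  expect_equal(dim(ep$data)[3], 256)          # 1 s at 256 Hz, half-open
  expect_equal(ep$time_ms[1], -51 / 256 * 1000)
  expect_equal(nrow(ep$skipped), 1)           # event at sample 10
  expect_equal(ep$skipped$reason, "boundary")
  expect_equal(ep$labels, c("b", "a"))        # labels follow their events
  # unusable events are not epoched
  ev$usable <- c(TRUE, FALSE, TRUE)
  ep2 <- extract_epochs(raw_from_matrix(data, 256, mont, ev))
  expect_equal(ep2$labels, "a")
  ev$usable <- FALSE
  expect_error(extract_epochs(raw_from_matrix(data, 256, mont, ev)),
               "no usable events")
})

test_that("baseline correction zeroes the baseline mean and refuses reuse", {
  ep <- noiseless_epochs("control")
  bl <- ep  # already baseline-corrected by the helper
  sel <- bl$time_ms >= -200 & bl$time_ms < 0
  expect_equal(max(abs(apply(bl$data[, , sel], c(1, 2), mean))), 0,
               tolerance = 1e-9)
  expect_error(baseline_correct(bl), "already applied")
  # constant epoch -> all zeros
  epc <- ep; epc$baseline_applied <- FALSE
  epc$data[] <- 7.5
  expect_equal(max(abs(baseline_correct(epc)$data)), 0)
  # linear ramp from -1 at -200 ms to +4 at 800 ms: baseline mean is the
  # ramp value at the baseline midpoint, so the corrected value at t is
  # slope * (t - midpoint)
  epr <- ep; epr$baseline_applied <- FALSE
  tms <- epr$time_ms
  ramp <- -1 + (tms - (-200)) * (4 - (-1)) / 1000
  epr$data <- array(rep(ramp, each = prod(dim(epr$data)[1:2])),
                    dim = dim(epr$data))
  out <- baseline_correct(epr)
  selb <- tms >= -200 & tms < 0
  expected_at_0 <- (0 - mean(tms[selb])) * 5 / 1000
  i0 <- which.min(abs(tms - 0))
  expect_equal(out$data[1, 1, i0], expected_at_0 + (tms[i0]) * 5 / 1000,
               tolerance = 1e-9)
  # idempotence of the correction map on its own output
  out2 <- out; out2$baseline_applied <- FALSE
  expect_equal(baseline_correct(out2)$data, out$data, tolerance = 1e-12)
})

test_that("artifact rejection applies both thresholds and reports retention", {
  ep <- noiseless_epochs("control")
  ep$data[3, 2, ] <- ep$data[3, 2, ] + 500 * sin(pi * seq_len(dim(ep$data)[3]) /
                                                   dim(ep$data)[3])
  out <- reject_artifacts(ep, ptp = 100, grad = 1e9)
  expect_true(out$rejected[3])
  expect_equal(out$reject_reason[3], "peak-to-peak")
  expect_false(any(out$rejected[-3]))
  # infinite thresholds reject nothing
  expect_false(any(reject_artifacts(ep, Inf, Inf)$rejected))
  # gradient-only violation
  epg <- noiseless_epochs("control")
  epg$data[1, 1, 100] <- epg$data[1, 1, 100] + 300
  outg <- reject_artifacts(epg, ptp = 1e9, grad = 75)
  expect_equal(outg$reject_reason[1], "gradient")
  # clean noisy epochs mostly retained at default thresholds
  s <- simulate_igt_session(igt_config(n_trials_per_version = 20,
                                       block_len = 10), seed = 2,
                            policy = "uniform-random")
  raw <- synthesize_eeg(s, erp_template("control"), tiny_montage(),
                        noise_rms = 5, blink_rate = 0, fs = 256, seed = 2)
  epn <- preprocess_eeg(raw, preproc_config())
  expect_gte(mean(!epn$rejected), 0.95)
  # manual override forces a trial back in
  ov <- stats::setNames(FALSE, out$trial_index[3])
  expect_false(reject_artifacts(ep, 100, 1e9, override = ov)$rejected[3])
})

test_that("a noiseless template survives the full chain nearly unchanged", {
  s <- simulate_igt_session(igt_config(n_trials_per_version = 10,
                                       block_len = 5), seed = 6,
                            policy = "uniform-random")
  mont <- tiny_montage()
  tpl <- erp_template("control")
  raw <- synthesize_eeg(s, tpl, mont, noise_rms = 0, blink_rate = 0,
                        fs = 1024, seed = 6)
  ep <- preprocess_eeg(raw, preproc_config())
  loss_tr <- condition_trials(ep, grep("^loss", unique(ep$labels), value = TRUE))
  wf <- colMeans(loss_tr)
  tms <- attr(loss_tr, "time_ms")
  # peak latency within one output sample of the template peak
  expect_lte(abs(tms[which.min(wf)] - tpl$peak_latency_ms), 1000 / 256 + 1e-9)
  # peak amplitude within 10% of the generated loss amplitude
  expect_lt(abs(min(wf) - tpl$base_amplitude_uv * tpl$gains[["loss"]]) ,
            0.1 * abs(tpl$base_amplitude_uv * tpl$gains[["loss"]]))
})

test_that("filtering and decimation commute on band-limited signals", {
  mont <- tiny_montage(4)
  fs <- 1024
  t <- seq(0, 8, by = 1 / fs)
  sig <- sin(2 * pi * 8 * t) + 0.5 * sin(2 * pi * 14 * t)
  raw <- raw_from_matrix(matrix(rep(sig, 6), 6, byrow = TRUE), fs, mont)
  a <- bandpass(downsample(raw, 256), 0.5, 20)
  b <- downsample(bandpass(raw, 0.5, 20), 256)
  mid <- seq(500, 1500)
  expect_lt(max(abs(a$data[1, mid] - b$data[1, mid])), 0.02)
})
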