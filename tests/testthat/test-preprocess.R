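test_that("calibration applies affine corrections per channel and is invertible", {
  rec <- random_record(n = 40, missing_frac = 0.1)
  ident <- calibration_table(gains = c(heart_rate = 1), offsets = c(heart_rate = 0))
  expect_equal(apply_calibration(rec, ident)$channels, rec$channels)

  shift <- calibration_table(offsets = c(heart_rate = 0.5))
  out <- apply_calibration(rec, shift)
  expect_equal(out$channels$heart_rate, rec$channels$heart_rate + 0.5)
  expect_identical(is.na(out$channels$heart_rate), is.na(rec$channels$heart_rate))

  set.seed(8)
  for (i in 1:3) {
    g <- runif(length(rec$channels), 0.8, 1.2)
    o <- runif(length(rec$channels), -1, 1)
    names(g) <- names(o) <- names(rec$channels)
    fwd <- calibration_table(g, o)
    inv <- calibration_table(setNames(1 / g, names(g)), setNames(-o / g, names(o)))
    back <- apply_calibration(apply_calibration(rec, fwd), inv)
    expect_equal(back$channels, rec$channels)
  }
  expect_error(apply_calibration(rec, calibration_table(gains = c(nope = 2))),
               "absent")
})

test_that("trailing moving average matches its definition and a per-index loop oracle", {
  expect_equal(trailing_moving_average(rep(3.3, 10), 4), rep(3.3, 10))
  expect_equal(trailing_moving_average(c(1, 2, 3, 4), 2), c(1, 1.5, 2.5, 3.5))

  loop_oracle <- function(x, w) {
    vapply(seq_along(x), function(i) {
      win <- x[max(1, i - w + 1):i]
      if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
    }, numeric(1))
  }
  set.seed(21)
  for (w in c(1, 3, 40, 60, 200)) {
    x <- rnorm(150)
    x[sample(150, 30)] <- NA
    expect_equal(trailing_moving_average(x, w), loop_oracle(x, w))
  }
})

test_that("zero-phase filter preserves DC, passes low frequencies without lag, and attenuates per the closed form", {
  fs <- 1; dt <- 1 / fs
  expect_equal(zero_phase_lowpass(rep(5, 200), 2, 0.1, dt), rep(5, 200),
               tolerance = 1e-8)

  t <- seq(0, 499, by = dt)
  lowf <- 0.005  # well below the 0.1 Hz cutoff
  x <- sin(2 * pi * lowf * t)
  y <- zero_phase_lowpass(x, 2, 0.1, dt)
  core <- 101:400  # ignore filtfilt end transients
  amp <- sd(y[core]) / sd(x[core])
  expect_equal(amp, 1, tolerance = 0.01)
  lag <- which.max(ccf(y[core], x[core], lag.max = 20, plot = FALSE)$acf) - 21
  expect_equal(lag, 0)

  highf <- 0.4  # 4x cutoff
  xh <- sin(2 * pi * highf * t)
  yh <- zero_phase_lowpass(xh, 2, 0.1, dt)
  h2 <- (1 / (1 + (highf / 0.1)^4))  # analog order-2 magnitude, squared pass
  expect_lt(sd(yh[core]) / sd(xh[core]), h2)
})

test_that("zero-phase filter handles gaps by interpolation or segment splitting and rejects bad cutoffs", {
  set.seed(3)
  x <- cumsum(rnorm(300))
  x[c(50, 150:160)] <- NA  # short gap interpolated, long gap splits
  y <- zero_phase_lowpass(x, 2, 0.02, 10)
  expect_identical(is.na(y), is.na(x))
  expect_error(zero_phase_lowpass(x, 2, 0.2, 10), "Nyquist")
})

test_that("heat-flux artifact removal uses a closed interval and removal counts match brute force", {
  expect_equal(clip_heat_flux(c(-50, 0, 250)), c(-50, 0, 250))
  expect_equal(clip_heat_flux(c(300, 301, -100, -101)),
               c(300, NA, -100, NA))
  set.seed(12)
  x <- runif(500, -400, 600)
  y <- clip_heat_flux(x)
  expect_equal(sum(is.na(y)), sum(x < -100 | x > 300))
  expect_equal(y[!is.na(y)], x[x >= -100 & x <= 300])
})

test_that("cross-correlation lag estimation finds the true delay and caps at max_lags", {
  set.seed(9)
  x <- as.numeric(stats::filter(rnorm(1200), 0.9, method = "recursive"))
  expect_equal(estimate_peak_lag(x, x, 200), 0L)

  delayed <- c(rep(x[1], 75), x[1:(1200 - 75)]) + rnorm(1200, 0, 0.02)
  expect_equal(estimate_peak_lag(delayed, x, 200), 75L)

  far <- c(rep(x[1], 250), x[1:(1200 - 250)])
  expect_lte(estimate_peak_lag(far, x, 200), 200L)

  expect_error(estimate_peak_lag(rep(1, 500), rep(2, 500), 200), "constant")
})

test_that("rectal lag alignment pairs rectal[t+lag] with predictors[t] and shortens the record", {
  n <- 1000
  chans <- data.frame(heart_rate = seq_len(n) + 0, rectal_temp = seq_len(n) + 1000)
  rec <- session_record(chans, phase = rep("cycling", n))
  expect_equal(apply_rectal_lag(rec, 0)$channels, rec$channels)

  out <- apply_rectal_lag(rec, 75)
  expect_equal(session_length(out), 925)
  expect_equal(out$channels$rectal_temp[1], rec$channels$rectal_temp[76])
  expect_equal(out$channels$heart_rate[1], rec$channels$heart_rate[1])
  expect_length(out$phase, 925)
  expect_error(apply_rectal_lag(session_record(chans[1:50, ]), 75), "not longer")
})

test_that("after alignment at the built-in delay the residual lag is zero", {
  s <- simulate_session(sim_config(rectal_mode = "model_faithful",
                                   rectal_noise_sd = 0, artifact_rate = 0,
                                   missing_rate = 0, cycling_max_min = 60),
                        1, 1, seed = 5)
  rec <- s$record
  # the generative predictor combination, as the simulator built it
  combo <- 0.0100 * trailing_moving_average(rec$channels$heart_rate, 60) +
    0.0837 * rec$channels$insulated_skin_temp_scapula
  # unnormalized cross-correlation is slightly biased on trending
  # signals; the estimate lands within a minute of the built-in delay
  est <- estimate_peak_lag(rec$channels$rectal_temp, combo, 200)
  expect_lte(abs(est - 75L), 6L)
  aligned <- apply_rectal_lag(rec, 75)
  combo_a <- combo[seq_len(session_length(aligned))]
  expect_equal(estimate_peak_lag(aligned$channels$rectal_temp, combo_a, 150), 0L)
})

test_that("the full chain maps an artifact-free constant record to a constant record", {
  rec <- record_at_means(n = 400)
  out <- preprocess_session(rec, preprocess_config())
  expect_equal(session_length(out), 325)  # 75-sample lag removed
  for (nm in names(out$channels)) {
    expect_equal(out$channels[[nm]], rep(rec$channels[[nm]][1],
                                         session_length(out)),
                 tolerance = 1e-8)
  }
})

test_that("preprocess config validates itself and resolves the cutoff against Nyquist", {
  expect_error(preprocess_config(hf_lower_limit = 400), "hf_lower_limit")
  cfg <- preprocess_config()
  expect_equal(coretemp:::resolve_cutoff_hz(cfg, 10), 0.02)   # 0.1 Hz input
  expect_equal(coretemp:::resolve_cutoff_hz(cfg, 0.5), 0.2)   # 2 Hz input
  expect_error(coretemp:::resolve_cutoff_hz(preprocess_config(butterworth_cutoff_hz = 0.2), 10),
               "Nyquist")
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("hr_window_points: 30", "hf_window_points: 20"), path)
  cfg2 <- read_preprocess_config(path)
  expect_equal(cfg2$hr_window_points, 30L)
  writeLines("bogus_key: 1", path)
  expect_error(read_preprocess_config(path), "unknown config key")
})
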