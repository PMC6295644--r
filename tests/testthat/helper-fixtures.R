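# in-code fixtures shared across test files

# small session with every predictor channel frozen at the published means
record_at_means <- function(n = 20) {
  tab <- component_score_model()$table
  chans <- as.data.frame(setNames(lapply(tab$mean, rep, n), tab$channel),
                         optional = TRUE)
  chans$rectal_temp <- rep(37.0, n)
  session_record(chans, participant_id = "MEANS", session_id = 1)
}

# random record with configurable missingness, for round-trip properties
random_record <- function(n = 50, n_chan = 4, missing_frac = 0.1,
                          with_phase = TRUE) {
  sites <- c("scapula", "rib", "sternum", "thigh", "calf", "hand")
  nms <- c(paste0("skin_temp_", sites[seq_len(n_chan - 1)]), "heart_rate")
  chans <- as.data.frame(setNames(
    lapply(nms, function(x) round(runif(n, 30, 40), 3)), nms), optional = TRUE)
  for (nm in nms) {
    miss <- runif(n) < missing_frac
    chans[[nm]][miss] <- NA_real_
  }
  phase <- if (with_phase) {
    rep(c("baseline_rest", "chamber_rest", "cycling", "recovery"),
        each = ceiling(n / 4))[seq_len(n)]
  } else NULL
  session_record(chans, participant_id = "RND", session_id = 2, phase = phase)
}

# uncorrelated two-latent-factor data: first half of the columns load on
# factor 1, second half on factor 2
two_factor_data <- function(n, p = 6, loading = 0.9) {
  f1 <- rnorm(n); f2 <- rnorm(n)
  sapply(seq_len(p), function(j) {
    f <- if (j <= p / 2) f1 else f2
    loading * f + sqrt(1 - loading^2) * rnorm(n)
  })
}

expect_session_equal <- function(a, b) {
  expect_equal(a$channels, b$channels)
  expect_identical(is.na(a$channels), is.na(b$channels))
  expect_equal(a$phase, b$phase)
  expect_equal(a$sample_period_s, b$sample_period_s)
  expect_identical(a$participant_id, b$participant_id)
  expect_identical(a$session_id, b$session_id)
}
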