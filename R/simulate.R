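# run code under a local RNG seed, restoring global RNG state afterwards
with_local_seed <- function(seed, code) {
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions: a two-session heat protocol
#' (15 min baseline seated rest, 15 min chamber rest, 20-60 min cycling
#' stopped when rectal temperature rises 1.5 degC above baseline or
#' reaches 38.5 degC, 30 min recovery) at 0.1 Hz; session 1 cycling at
#' 75% of the participant's maximal heart rate, session 2 at 50%; 18
#' predictor channels whose means/SDs match the published development
#' statistics, driven by two latent processes (a skin-temperature
#' factor and a heat-flux factor); rectal temperature trailing the
#' predictors by 75 samples (12.5 min); occasional heat-flux artifacts
#' outside \[-100, 300\] W/m2; and per-channel missing runs.
#'
#' Two rectal generation modes exist because the real generative
#' process is unknown: `"physical"` (rectal follows the lagged,
#' smoothed thermal drive) gives realistic traces; `"model_faithful"`
#' (rectal at time t+75 is the published Min-Input equation evaluated
#' on smoothed heart rate and insulated scapula temperature at time t,
#' plus Gaussian noise) gives exact oracles for the prediction path.
#'
#' @param n_participants Number of participants (default 13).
#' @param n_single_session How many participants (taken from the end of
#'   the roster) complete only session 1 (default 1, as in the study
#'   flow: 12 of 13 completed both sessions).
#' @param rectal_mode `"physical"` or `"model_faithful"`.
#' @param rectal_noise_sd SD of rectal noise (degC; model-faithful mode).
#' @param channel_noise_scale Multiplier on channel-specific residual
#'   noise (1 = published SDs).
#' @param artifact_rate Per-sample probability of a heat-flux artifact.
#' @param missing_rate Per-channel fraction of samples made missing (in
#'   runs of about 10 samples).
#' @param baseline_rectal_c Baseline rectal temperature (degC).
#' @param rise_cap_c,ceiling_c Exercise stop rule: rise above baseline
#'   (degC) and absolute ceiling (degC).
#' @param cycling_min_min,cycling_max_min Cycling duration bounds (min).
#' @param hrmax_mean,hrmax_sd Participant HRmax distribution (beats/min).
#' @param hr_fractions Cycling intensity per session (fraction of HRmax).
#' @param rectal_lag_points Rectal delay behind the predictors (samples).
#' @param ar_coef AR(1) coefficient of slow channel noise at 0.1 Hz.
#' @param sample_period_s Sampling period (s).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_participants = 13L,
                       n_single_session = 1L,
                       rectal_mode = c("physical", "model_faithful"),
                       rectal_noise_sd = 0.05,
                       channel_noise_scale = 1,
                       artifact_rate = 0.01,
                       missing_rate = 0.02,
                       baseline_rectal_c = 37.0,
                       rise_cap_c = 1.5,
                       ceiling_c = 38.5,
                       cycling_min_min = 20,
                       cycling_max_min = 60,
                       hrmax_mean = 181,
                       hrmax_sd = 9,
                       hr_fractions = c(0.75, 0.50),
                       rectal_lag_points = 75L,
                       ar_coef = 0.95,
                       sample_period_s = 10) {
  rectal_mode <- match.arg(rectal_mode)
  stopifnot(n_participants >= 1, n_single_session >= 0,
            n_single_session <= n_participants,
            rectal_lag_points >= 0, artifact_rate >= 0, artifact_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            cycling_min_min > 0, cycling_max_min >= cycling_min_min)
  structure(list(n_participants = as.integer(n_participants),
                 n_single_session = as.integer(n_single_session),
                 rectal_mode = rectal_mode,
                 rectal_noise_sd = rectal_noise_sd,
                 channel_noise_scale = channel_noise_scale,
                 artifact_rate = artifact_rate,
                 missing_rate = missing_rate,
                 baseline_rectal_c = baseline_rectal_c,
                 rise_cap_c = rise_cap_c, ceiling_c = ceiling_c,
                 cycling_min_min = cycling_min_min,
                 cycling_max_min = cycling_max_min,
                 hrmax_mean = hrmax_mean, hrmax_sd = hrmax_sd,
                 hr_fractions = hr_fractions,
                 rectal_lag_points = as.integer(rectal_lag_points),
                 ar_coef = ar_coef,
                 sample_period_s = sample_period_s),
            class = "sim_config")
}

# unit-variance AR(1) noise
ar1_noise <- function(n, coef) {
  x <- stats::filter(stats::rnorm(n, sd = sqrt(1 - coef^2)), coef,
                     method = "recursive",
                     init = stats::rnorm(1))
  as.numeric(x)
}

# primary factor loading per channel (published rotated loadings:
# component 1 for temperatures, component 2 for heat fluxes)
.sim_loadings <- c(
  skin_temp_scapula = 0.955, skin_temp_forearm = 0.954,
  skin_temp_radial = 0.921, skin_temp_thigh = 0.917,
  skin_temp_calf = 0.914, skin_temp_hand = 0.914, skin_temp_arm = 0.899,
  skin_temp_sternum = 0.881, skin_temp_rib = 0.858,
  insulated_skin_temp_rib = 0.809, skin_temp_forehead = 0.803,
  insulated_skin_temp_radial = 0.921, insulated_skin_temp_scapula = 0.901,
  insulated_skin_temp_sternum = 0.883,
  heat_flux_scapula = 0.905, heat_flux_rib = 0.856, heat_flux_sternum = 0.850)

#' Simulate one heat session
#'
#' Generates a protocol-faithful participant-session (see [sim_config()])
#' together with its ground truth: true phase boundaries, lag, injected
#' artifact and missing indices, and the generative coefficients.
#'
#' @param config A [sim_config()].
#' @param participant Participant number (1-based).
#' @param session Session number (1 or 2).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return List with `record` (a [session_record()]) and `truth`.
#' @export
simulate_session <- function(config = sim_config(), participant = 1L,
                             session = 1L, seed = 1L) {
  stopifnot(session %in% c(1L, 2L))
  with_local_seed(seed, simulate_session_impl(config, participant, session, seed))
}

simulate_session_impl <- function(config, participant, session, seed) {
  spm <- 60 / config$sample_period_s  # samples per minute
  lag <- config$rectal_lag_points

  # participant-level physiology (same across that participant's sessions)
  hrmax <- with_local_seed(1e6L + participant,
                           stats::rnorm(1, config$hrmax_mean, config$hrmax_sd))
  hr_cycle <- config$hr_fractions[session] * hrmax

  # rectal heating rate during cycling (degC/min): session 1 is hotter
  rate <- max(0.01, stats::rnorm(1,
                                 mean = if (session == 1) 0.036 else 0.023,
                                 sd = if (session == 1) 0.008 else 0.005))
  n_base <- as.integer(15 * spm)
  n_chamber <- as.integer(15 * spm)
  n_rec <- as.integer(30 * spm)

  # first-passage stop rule on the deterministic core drive, capped
  max_cyc <- as.integer(config$cycling_max_min * spm)
  rise_cyc <- rate * (seq_len(max_cyc) / spm)
  chamber_rise <- 0.05  # passive rise while resting in the chamber
  stop_at <- which(chamber_rise + rise_cyc >= config$rise_cap_c |
                   config$baseline_rectal_c + chamber_rise + rise_cyc >= config$ceiling_c)
  n_cyc <- if (length(stop_at)) min(stop_at[1], max_cyc) else max_cyc
  n_cyc <- max(n_cyc, as.integer(config$cycling_min_min * spm))

  n <- n_base + n_chamber + n_cyc + n_rec
  phase <- rep(c("baseline_rest", "chamber_rest", "cycling", "recovery"),
               c(n_base, n_chamber, n_cyc, n_rec))
  in_chamber <- phase %in% c("chamber_rest", "cycling")
  t_cyc <- cumsum(phase == "cycling") / spm          # minutes of cycling so far
  t_rec <- cumsum(phase == "recovery") / spm         # minutes of recovery so far

  # core rise above baseline (deterministic drive)
  rise <- chamber_rise * pmin(1, cumsum(in_chamber) / (5 * spm)) +
    rate * t_cyc
  peak <- rise[n_base + n_chamber + n_cyc]
  rise[phase == "recovery"] <- 0.2 + (peak - 0.2) * exp(-t_rec[phase == "recovery"] / 20)

  # latent factor 1: skin-thermal drive (chamber heat + exercise, slow)
  f1_drive <- pmin(1, cumsum(in_chamber) / (10 * spm)) +
    0.8 * pmin(1, t_cyc / 15)
  f1_drive[phase == "recovery"] <-
    f1_drive[n_base + n_chamber + n_cyc] * exp(-t_rec[phase == "recovery"] / 25)
  # latent factor 2: skin heat-loss drive. Unlike the skin-temperature
  # factor it drops on entering the 35 degC chamber (smaller skin-air
  # gradient), recovers with sweat evaporation during cycling, and
  # spikes when the hot participant returns to 23 degC air.
  f2_drive <- 0.3 - 0.8 * pmin(1, cumsum(in_chamber) / (5 * spm)) +
    1.1 * pmin(1, t_cyc / 10)
  f2_drive[phase == "recovery"] <-
    1.6 * exp(-t_rec[phase == "recovery"] / 10)

  standardize <- function(x) (x - mean(x)) / max(stats::sd(x), 1e-12)
  f1 <- standardize(f1_drive + 0.15 * ar1_noise(n, config$ar_coef))
  f2 <- standardize(f2_drive + 0.25 * ar1_noise(n, config$ar_coef))

  # heart rate: phase targets + AR(1) noise. Seated rest in 35 degC air
  # and recovery from exhausting exercise both keep HR well above cool
  # resting values.
  hr_target <- rep(75, n)
  hr_target[phase == "chamber_rest"] <- 95
  hr_target[phase == "cycling"] <- hr_cycle
  hr_target[phase == "recovery"] <-
    95 + (hr_cycle - 95) * exp(-t_rec[phase == "recovery"] / 10)
  # first-order approach to target (~1 min time constant)
  hr <- stats::filter(hr_target * 0.1, 0.9, method = "recursive",
                      init = hr_target[1])
  hr <- as.numeric(hr) + 3 * ar1_noise(n, config$ar_coef)

  tab <- .score_table
  channels <- data.frame(row.names = seq_len(n))
  for (i in seq_len(nrow(tab))) {
    ch <- tab$channel[i]
    if (ch == "heart_rate") { channels[[ch]] <- hr; next }
    lam <- .sim_loadings[[ch]]
    fac <- if (is_heat_flux(ch)) f2 else f1
    eps <- ar1_noise(n, config$ar_coef)
    channels[[ch]] <- tab$mean[i] + tab$sd[i] *
      (lam * fac + config$channel_noise_scale * sqrt(1 - lam^2) * eps)
  }

  hr_smoothed <- trailing_moving_average(hr, 60L)
  t_ins_scap <- channels$insulated_skin_temp_scapula
  rectal <- if (config$rectal_mode == "model_faithful") {
    eps <- if (config$rectal_noise_sd > 0) stats::rnorm(n, 0, config$rectal_noise_sd) else 0
    base <- 0.0100 * hr_smoothed + 0.0837 * t_ins_scap + 33.1735 + eps
    if (lag > 0) c(rep(base[1], lag), base[seq_len(n - lag)]) else base
  } else {
    core <- config$baseline_rectal_c +
      pmin(rise, min(config$rise_cap_c, config$ceiling_c - config$baseline_rectal_c))
    lagged <- if (lag > 0) c(rep(core[1], lag), core[seq_len(n - lag)]) else core
    # stop rule keeps the participant at or below the ceiling
    pmin(trailing_moving_average(lagged, 12L) +
           stats::rnorm(n, 0, config$rectal_noise_sd),
         config$ceiling_c)
  }
  channels$rectal_temp <- rectal

  # heat-flux artifacts: spikes outside the [-100, 300] W/m2 window
  artifact_idx <- list()
  for (ch in grep("^heat_flux", names(channels), value = TRUE)) {
    k <- stats::rbinom(1, n, config$artifact_rate)
    idx <- sort(sample.int(n, k))
    if (k) {
      spike <- ifelse(stats::runif(k) < 0.7,
                      300 + stats::runif(k, 10, 400),
                      -100 - stats::runif(k, 10, 200))
      channels[[ch]][idx] <- spike
    }
    artifact_idx[[ch]] <- idx
  }

  # missing runs (mean length 10) per channel
  missing_idx <- list()
  if (config$missing_rate > 0) {
    for (ch in names(channels)) {
      target <- config$missing_rate * n
      idx <- integer()
      while (length(idx) < target) {
        start <- sample.int(n, 1)
        len <- 1 + stats::rgeom(1, 1 / 10)
        idx <- union(idx, seq.int(start, min(n, start + len - 1L)))
      }
      idx <- sort(idx)
      channels[[ch]][idx] <- NA_real_
      missing_idx[[ch]] <- idx
    }
  }

  record <- session_record(channels,
                           participant_id = sprintf("P%02d", participant),
                           session_id = session,
                           sample_period_s = config$sample_period_s,
                           phase = phase)
  truth <- list(phases = session_phases(record),
                lag = lag,
                rectal_mode = config$rectal_mode,
                coefficients = c(heart_rate = 0.0100,
                                 insulated_skin_temp_scapula = 0.0837,
                                 intercept = 33.1735),
                hrmax = hrmax,
                cycling_min = n_cyc / spm,
                artifact_idx = artifact_idx,
                missing_idx = missing_idx,
                seed = seed)
  list(record = record, truth = truth)
}

cohort_session_plan <- function(config) {
  full <- config$n_participants - config$n_single_session
  n_sessions <- ifelse(seq_len(config$n_participants) <= full, 2L, 1L)
  data.frame(participant = rep(seq_len(config$n_participants), n_sessions),
             session = unlist(lapply(n_sessions, seq_len)))
}

cohort_subseed <- function(seed, participant, session) {
  as.integer((as.numeric(seed) * 97 + participant * 131 + session) %% 2147483647)
}

#' Simulate a cohort in memory
#'
#' Generates all participant-sessions of a cohort (12 two-session
#' participants plus 1 single-session participant under the defaults)
#' with deterministic per-session sub-seeds derived from the master
#' seed.
#'
#' @param config A [sim_config()].
#' @param seed Master seed.
#' @return List of `list(record, truth)` entries, one per session.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  plan <- cohort_session_plan(config)
  lapply(seq_len(nrow(plan)), function(i) {
    simulate_session(config, plan$participant[i], plan$session[i],
                     cohort_subseed(seed, plan$participant[i], plan$session[i]))
  })
}

#' @rdname simulate_cohort
#' @param dir Output directory (created if needed); one CSV per
#'   session plus `manifest.csv` and `truth.csv`.
#' @return `write_cohort` invisibly returns the manifest data frame.
#' @export
write_cohort <- function(config = sim_config(), dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sessions <- simulate_cohort(config, seed)
  rows <- lapply(sessions, function(s) {
    r <- s$record
    file <- sprintf("%s_s%d.csv", r$participant_id, r$session_id)
    write_session(r, file.path(dir, file))
    data.frame(participant_id = r$participant_id, session_id = r$session_id,
               file = file, seed = s$truth$seed,
               n_samples = session_length(r),
               cycling_min = s$truth$cycling_min,
               hrmax = s$truth$hrmax,
               rectal_mode = s$truth$rectal_mode,
               lag = s$truth$lag,
               n_artifacts = sum(lengths(s$truth$artifact_idx)),
               n_missing = sum(lengths(s$truth$missing_idx)))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest[c("participant_id", "session_id", "file", "seed",
                              "n_samples")],
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(manifest, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(manifest)
}
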