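#' Preprocessing configuration
#'
#' Parameters of the signal-conditioning chain. At the native 0.1 Hz
#' sampling rate the defaults correspond to a 10-min (60-point) trailing
#' heart-rate smoother, a 6.7-min (40-point) trailing heat-flux
#' smoother, heat-flux artifact limits of \[-100, 300\] W/m2 (closed
#' interval; boundary samples retained), and a 75-sample (12.5-min)
#' rectal lag.
#'
#' The Butterworth cutoff defaults to `NULL` = automatic: the nominal
#' 0.2 Hz low-pass is used whenever the input sampling rate admits it
#' (Nyquist > 0.2 Hz); for slower inputs, including the native 0.1 Hz
#' logging rate whose Nyquist frequency is 0.05 Hz, the cutoff falls
#' back to 0.4x Nyquist (0.02 Hz at 0.1 Hz). An explicit cutoff at or
#' above Nyquist is a configuration error.
#'
#' @param hr_window_points Trailing heart-rate window (samples).
#' @param hf_window_points Trailing heat-flux window (samples).
#' @param butterworth_order Butterworth filter order (applied
#'   forward-backward, so effective attenuation is that of twice the
#'   order).
#' @param butterworth_cutoff_hz Low-pass cutoff in Hz, or `NULL` for
#'   automatic selection as described above.
#' @param hf_lower_limit,hf_upper_limit Heat-flux artifact limits (W/m2).
#' @param rectal_lag_points Rectal-vs-predictor delay in samples.
#' @param max_lags Largest lag searched by [estimate_peak_lag()].
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(hr_window_points = 60L,
                              hf_window_points = 40L,
                              butterworth_order = 2L,
                              butterworth_cutoff_hz = NULL,
                              hf_lower_limit = -100,
                              hf_upper_limit = 300,
                              rectal_lag_points = 75L,
                              max_lags = 200L) {
  stopifnot(hr_window_points >= 1, hf_window_points >= 1,
            butterworth_order >= 1,
            hf_lower_limit < hf_upper_limit,
            rectal_lag_points >= 0, max_lags >= rectal_lag_points)
  structure(list(hr_window_points = as.integer(hr_window_points),
                 hf_window_points = as.integer(hf_window_points),
                 butterworth_order = as.integer(butterworth_order),
                 butterworth_cutoff_hz = butterworth_cutoff_hz,
                 hf_lower_limit = hf_lower_limit,
                 hf_upper_limit = hf_upper_limit,
                 rectal_lag_points = as.integer(rectal_lag_points),
                 max_lags = as.integer(max_lags)),
            class = "preprocess_config")
}

#' @rdname preprocess_config
#' @param path Path to a YAML file whose keys are a subset of the
#'   `preprocess_config()` arguments.
#' @export
read_preprocess_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(preprocess_config)))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  do.call(preprocess_config, vals)
}

resolve_cutoff_hz <- function(config, sample_period_s) {
  nyquist <- 1 / (2 * sample_period_s)
  cutoff <- config$butterworth_cutoff_hz
  if (is.null(cutoff)) {
    cutoff <- if (nyquist > 0.2) 0.2 else 0.4 * nyquist
  }
  if (cutoff <= 0 || cutoff >= nyquist) {
    stop(sprintf(paste0("Butterworth cutoff %g Hz is not below the Nyquist ",
                        "frequency %g Hz of the input; supply data sampled ",
                        "faster or a lower cutoff (e.g. %g Hz)"),
                 cutoff, nyquist, 0.4 * nyquist), call. = FALSE)
  }
  cutoff
}

#' Sensor calibration tables
#'
#' Applies precomputed affine calibration corrections
#' (`value -> gain * value + offset`) per channel. Missing samples stay
#' missing.
#'
#' @param gains,offsets Named numeric vectors keyed by channel name;
#'   channels named in `offsets` but not `gains` get gain 1.
#' @return A `calibration_table`.
#' @examples
#' tab <- calibration_table(gains = c(heat_flux_rib = 1.02),
#'                          offsets = c(heat_flux_rib = -0.5))
#' @export
calibration_table <- function(gains = numeric(), offsets = numeric()) {
  channels <- union(names(gains), names(offsets))
  g <- ifelse(channels %in% names(gains), gains[channels], 1)
  o <- ifelse(channels %in% names(offsets), offsets[channels], 0)
  names(g) <- names(o) <- channels
  if (any(!is.finite(g)) || any(g == 0)) {
    stop("calibration gains must be finite and nonzero", call. = FALSE)
  }
  structure(list(gains = g, offsets = o), class = "calibration_table")
}

#' @rdname calibration_table
#' @param record A [session_record()].
#' @param table A `calibration_table`.
#' @export
apply_calibration <- function(record, table) {
  absent <- setdiff(names(table$gains), names(record$channels))
  if (length(absent)) stop("calibration references absent channel(s): ",
                           paste(absent, collapse = ", "), call. = FALSE)
  for (nm in names(table$gains)) {
    record$channels[[nm]] <-
      table$gains[[nm]] * record$channels[[nm]] + table$offsets[[nm]]
  }
  record
}

#' Trailing moving average
#'
#' Causal smoother: each output sample is the mean of the present values
#' in the window of `window_points` samples ending at (and including)
#' the current sample. The window shrinks at the start of the series;
#' output is missing only where the window holds no present value.
#'
#' @param series Numeric vector, `NA` = missing.
#' @param window_points Window length in samples (>= 1).
#' @return Numeric vector of the same length.
#' @examples
#' trailing_moving_average(c(1, 2, 3, 4), 2)  # 1, 1.5, 2.5, 3.5
#' @export
trailing_moving_average <- function(series, window_points) {
  stopifnot(window_points >= 1)
  w <- as.integer(window_points)
  n <- length(series)
  present <- !is.na(series)
  vals <- ifelse(present, series, 0)
  csum <- cumsum(vals)
  ccnt <- cumsum(as.numeric(present))
  i <- seq_len(n)
  lo <- pmax(i - w, 0L)
  s <- csum[i] - c(0, csum)[lo + 1L]
  k <- ccnt[i] - c(0, ccnt)[lo + 1L]
  out <- ifelse(k > 0, s / k, NA_real_)
  out
}

#' Zero-phase Butterworth low-pass filtering
#'
#' Applies an order-`order` Butterworth low-pass forward and backward
#' (`signal::filtfilt`), cancelling phase delay; the effective magnitude
#' response is the squared single-pass response. Interior gaps of up to
#' `max_interp_gap` samples are bridged by linear interpolation before
#' filtering and re-marked missing afterwards; longer gaps (and leading/
#' trailing missingness) split the series into independently filtered
#' contiguous segments.
#'
#' @param series Numeric vector (`NA` = missing).
#' @param order Filter order.
#' @param cutoff_hz Cutoff frequency in Hz; must lie below Nyquist.
#' @param sample_period_s Sampling period in seconds.
#' @param max_interp_gap Largest interior gap (samples) bridged by
#'   interpolation rather than segment splitting.
#' @return Filtered vector, same length, missing where input was missing.
#' @export
zero_phase_lowpass <- function(series, order, cutoff_hz, sample_period_s,
                               max_interp_gap = 5L) {
  nyquist <- 1 / (2 * sample_period_s)
  if (cutoff_hz <= 0 || cutoff_hz >= nyquist) {
    stop(sprintf("cutoff %g Hz must lie strictly between 0 and the Nyquist frequency %g Hz",
                 cutoff_hz, nyquist), call. = FALSE)
  }
  w <- cutoff_hz / nyquist
  bf <- signal::butter(order, w, type = "low")
  # odd-reflection padding long enough for the startup transient to die
  pad <- max(24L, ceiling(12 / w))
  out <- rep(NA_real_, length(series))
  was_na <- is.na(series)
  for (seg in filter_segments(series, max_interp_gap)) {
    x <- series[seg]
    nas <- which(is.na(x))
    if (length(nas)) {  # interior gaps <= max_interp_gap by construction
      x <- stats::approx(seq_along(x)[-nas], x[-nas], xout = seq_along(x))$y
    }
    n <- length(x)
    if (n <= 3 * (order + 1)) { out[seg] <- x; next }  # too short to filter
    k <- min(pad, n - 1L)
    padded <- c(2 * x[1] - x[(k + 1):2], x, 2 * x[n] - x[(n - 1):(n - k)])
    y <- signal::filtfilt(bf, padded)
    out[seg] <- y[(k + 1):(k + n)]
  }
  out[was_na] <- NA_real_
  out
}

# contiguous index runs treating interior gaps <= max_gap as part of a run
filter_segments <- function(series, max_gap) {
  present <- which(!is.na(series))
  if (!length(present)) return(list())
  breaks <- which(diff(present) > max_gap + 1L)
  starts <- present[c(1L, breaks + 1L)]
  ends <- present[c(breaks, length(present))]
  mapply(seq.int, starts, ends, SIMPLIFY = FALSE)
}

#' Heat-flux artifact removal
#'
#' Samples outside the closed interval `[lower, upper]` are removed
#' (become missing), not truncated; boundary values are retained.
#'
#' @param series Numeric vector (W/m2).
#' @param lower,upper Artifact limits, `lower < upper`.
#' @return Vector with out-of-range samples set missing.
#' @examples
#' clip_heat_flux(c(-150, 0, 300, 301), -100, 300)  # NA 0 300 NA
#' @export
clip_heat_flux <- function(series, lower = -100, upper = 300) {
  stopifnot(lower < upper)
  series[!is.na(series) & (series < lower | series > upper)] <- NA_real_
  series
}

#' Cross-correlation lag estimation
#'
#' Finds the non-negative lag (in samples) at which the mean-removed
#' cross-correlation between a reference series and a predictor series
#' peaks. A positive lag means the reference trails the predictor. Ties
#' break toward the smallest lag. Intended for estimating the delay of
#' rectal temperature behind skin temperatures and heart rate.
#'
#' @param reference,predictor Gap-free numeric vectors of equal length.
#' @param max_lags Largest lag searched (default 200).
#' @return Integer lag in `[0, max_lags]`.
#' @export
estimate_peak_lag <- function(reference, predictor, max_lags = 200L) {
  n <- length(reference)
  stopifnot(length(predictor) == n, n >= 2L * max_lags)
  if (anyNA(reference) || anyNA(predictor)) {
    stop("estimate_peak_lag requires gap-free input", call. = FALSE)
  }
  r <- reference - mean(reference)
  p <- predictor - mean(predictor)
  if (all(r == 0) || all(p == 0)) {
    stop("constant input: cross-correlation undefined", call. = FALSE)
  }
  cc <- vapply(0:max_lags, function(lag) {
    sum(r[(lag + 1L):n] * p[1:(n - lag)])
  }, numeric(1))
  as.integer(which.max(cc) - 1L)  # which.max takes the first maximum: smallest lag
}

#' Rectal lag alignment
#'
#' Advances the rectal channel by `lag_points` samples so that the
#' rectal value at time `t + lag` is paired with the predictor values at
#' time `t`, discarding the unpaired tail; the record shortens by
#' `lag_points` samples and phase annotations follow the predictor time
#' base.
#'
#' @param record A [session_record()] containing a `rectal_temp` channel.
#' @param lag_points Delay in samples (default 75 = 12.5 min at 0.1 Hz).
#' @return The lag-aligned, shortened record.
#' @export
apply_rectal_lag <- function(record, lag_points = 75L) {
  lag <- as.integer(lag_points)
  n <- session_length(record)
  stopifnot(lag >= 0)
  if (n <= lag) stop("record (", n, " samples) not longer than lag ", lag,
                     call. = FALSE)
  if (!"rectal_temp" %in% names(record$channels)) {
    stop("record has no rectal_temp channel", call. = FALSE)
  }
  if (lag == 0L) return(record)
  keep <- seq_len(n - lag)
  rect <- record$channels$rectal_temp[keep + lag]
  record$channels <- record$channels[keep, , drop = FALSE]
  record$channels$rectal_temp <- rect
  rownames(record$channels) <- NULL
  if (!is.null(record$phase)) record$phase <- record$phase[keep]
  record
}

#' Full signal-conditioning chain
#'
#' Applies, in order: calibration (if supplied), heart-rate trailing
#' smoothing, heat-flux zero-phase Butterworth low-pass, heat-flux
#' artifact removal, heat-flux trailing smoothing, and rectal lag
#' alignment. Temperatures are not smoothed. Complete-case filtering is
#' left to the caller (prediction does not require it; development and
#' screening do).
#'
#' @param record A [session_record()].
#' @param config A [preprocess_config()].
#' @param calibration Optional [calibration_table()].
#' @param verbose Emit per-step messages with samples removed.
#' @return The preprocessed (lag-aligned) record.
#' @export
preprocess_session <- function(record, config = preprocess_config(),
                               calibration = NULL, verbose = FALSE) {
  if (!is.null(calibration)) record <- apply_calibration(record, calibration)
  if ("heart_rate" %in% names(record$channels)) {
    record$channels$heart_rate <-
      trailing_moving_average(record$channels$heart_rate, config$hr_window_points)
  }
  hf <- names(record$channels)[vapply(names(record$channels), is_heat_flux, logical(1))]
  if (length(hf)) {
    cutoff <- resolve_cutoff_hz(config, record$sample_period_s)
    for (nm in hf) {
      x <- record$channels[[nm]]
      x <- zero_phase_lowpass(x, config$butterworth_order, cutoff,
                              record$sample_period_s)
      n_before <- sum(!is.na(x))
      x <- clip_heat_flux(x, config$hf_lower_limit, config$hf_upper_limit)
      if (verbose) message(sprintf("%s: %d artifact sample(s) removed",
                                   nm, n_before - sum(!is.na(x))))
      record$channels[[nm]] <- trailing_moving_average(x, config$hf_window_points)
    }
  }
  if ("rectal_temp" %in% names(record$channels) && config$rectal_lag_points > 0) {
    record <- apply_rectal_lag(record, config$rectal_lag_points)
  }
  record
}
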