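# Published model constants: per-channel component score coefficients,
# development-set means and SDs (18 predictors), and the two regression
# equations with their systematic offsets. Stored at full printed
# precision; never re-rounded.
.score_table <- data.frame(
  channel = c("skin_temp_scapula", "skin_temp_forearm", "skin_temp_radial",
              "skin_temp_thigh", "skin_temp_calf", "skin_temp_hand",
              "skin_temp_arm", "skin_temp_sternum", "skin_temp_rib",
              "insulated_skin_temp_rib", "skin_temp_forehead",
              "insulated_skin_temp_radial", "insulated_skin_temp_scapula",
              "insulated_skin_temp_sternum", "heart_rate",
              "heat_flux_scapula", "heat_flux_rib", "heat_flux_sternum"),
  coef1 = c(0.099, 0.094, 0.115, 0.073, 0.075, 0.096, 0.077, 0.066, 0.061,
            0.042, 0.127, 0.077, 0.064, 0.060, 0.023, -0.064, -0.062, -0.088),
  coef2 = c(-0.061, -0.047, -0.127, 0.016, 0.010, -0.066, -0.001, 0.029, 0.041,
            0.091, -0.206, 0.005, 0.042, 0.051, 0.116, 0.292, 0.278, 0.299),
  mean = c(35.69, 34.86, 34.63, 34.87, 33.91, 34.06, 35.21, 36.05, 35.77,
           36.27, 35.10, 35.65, 36.52, 36.37, 111.3, 54.46, 32.43, 18.03),
  sd = c(1.55, 1.95, 2.11, 1.88, 2.01, 2.53, 1.90, 1.41, 1.37,
         1.40, 1.42, 1.96, 1.35, 1.32, 34.1, 70.88, 42.65, 21.61),
  stringsAsFactors = FALSE
)

#' Component-score models
#'
#' A component-score model carries, for each of the 18 predictor
#' channels, the score coefficients of the two retained principal
#' components together with the development-set mean and SD used to
#' standardize incoming values. The score of component c for an
#' observation x is
#' \deqn{s_c = \sum_{k} w_{ck} (x_k - \bar x_k) / SD_k,}
#' so an observation at the stored means scores exactly (0, 0).
#' `component_score_model()` with no arguments returns the shipped
#' published model.
#'
#' @param table Data frame with columns `channel`, `coef1`, `coef2`,
#'   `mean`, `sd` (one row per predictor; SDs > 0).
#' @return A `component_score_model`.
#' @examples
#' m <- component_score_model()
#' obs <- setNames(as.list(m$table$mean), m$table$channel)
#' component_scores(obs, m)  # both zero
#' @export
component_score_model <- function(table = .score_table) {
  stopifnot(all(c("channel", "coef1", "coef2", "mean", "sd") %in% names(table)),
            !anyDuplicated(table$channel), all(table$sd > 0),
            all(is.finite(table$coef1)), all(is.finite(table$coef2)))
  structure(list(table = table), class = "component_score_model")
}

#' Component scores for observations
#'
#' Evaluates the two component scores for one observation (named list /
#' vector) or many (data frame with one column per channel).
#'
#' @param observation Named numeric vector, named list, or data frame
#'   containing every channel of the model.
#' @param model A [component_score_model()].
#' @return A list (`score1`, `score2`); vectors when `observation` has
#'   multiple rows.
#' @export
component_scores <- function(observation, model = component_score_model()) {
  tab <- model$table
  obs <- as.data.frame(as.list(observation), optional = TRUE)
  missing_ch <- setdiff(tab$channel, names(obs))
  if (length(missing_ch)) {
    stop("observation lacks channel(s): ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  z <- mapply(function(ch, m, s) (obs[[ch]] - m) / s,
              tab$channel, tab$mean, tab$sd)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  list(score1 = drop(z %*% tab$coef1), score2 = drop(z %*% tab$coef2))
}

#' Linear prediction models
#'
#' A named linear equation for rectal temperature: coefficients over
#' input names (channel names or `score1`/`score2`), an intercept, and a
#' systematic offset. The offset is the mean difference
#' (predicted - measured) observed on validation data; offset correction
#' subtracts it from the raw prediction.
#'
#' `max_input_model()` and `min_input_model()` return the two published
#' equations; `external_linear_model()` wraps a user-supplied prior
#' model (its published offset is +0.24 degC).
#'
#' @param name Model label.
#' @param terms Named numeric vector of coefficients.
#' @param intercept Intercept (degC).
#' @param offset Systematic offset (degC), subtracted when correcting.
#' @return A `linear_prediction_model`.
#' @export
linear_prediction_model <- function(name, terms, intercept, offset = 0) {
  stopifnot(is.numeric(terms), !is.null(names(terms)), all(nzchar(names(terms))),
            all(is.finite(terms)), is.finite(intercept), is.finite(offset))
  structure(list(name = name, terms = terms, intercept = intercept,
                 offset = offset),
            class = "linear_prediction_model")
}

#' @rdname linear_prediction_model
#' @export
max_input_model <- function() {
  linear_prediction_model("max_input",
                          c(score1 = 0.2978, score2 = 0.2471),
                          intercept = 37.2539, offset = -0.15)
}

#' @rdname linear_prediction_model
#' @export
min_input_model <- function() {
  linear_prediction_model("min_input",
                          c(heart_rate = 0.0100,
                            insulated_skin_temp_scapula = 0.0837),
                          intercept = 33.1735, offset = -0.06)
}

#' @rdname linear_prediction_model
#' @export
external_linear_model <- function(terms, intercept, offset = 0.24,
                                  name = "external") {
  linear_prediction_model(name, terms, intercept, offset)
}

#' @export
print.linear_prediction_model <- function(x, ...) {
  eq <- paste(sprintf("%.4g x %s", x$terms, names(x$terms)), collapse = " + ")
  cat(sprintf("<%s model: T = %s + %.4f; offset %+.2f degC>\n",
              x$name, eq, x$intercept, x$offset))
  invisible(x)
}

evaluate_linear_model <- function(inputs, model, correct_offset = FALSE) {
  raw <- rep(model$intercept, length(inputs[[1]]))
  for (nm in names(model$terms)) raw <- raw + model$terms[[nm]] * inputs[[nm]]
  if (correct_offset) raw - model$offset else raw
}

#' Published prediction equations
#'
#' `predict_max_input()` evaluates the component-score regression
#' T = 0.2978 s1 + 0.2471 s2 + 37.2539; `predict_min_input()` evaluates
#' T = 0.0100 HR + 0.0837 T_ins_scapula + 33.1735. With
#' `correct_offset = TRUE` the model's systematic offset (-0.15 and
#' -0.06 degC respectively) is subtracted from the raw prediction.
#'
#' @param score1,score2 Component scores (see [component_scores()]).
#' @param model The corresponding [linear_prediction_model()].
#' @param correct_offset Subtract the stored systematic offset?
#' @return Predicted rectal temperature (degC).
#' @examples
#' predict_max_input(0, 0)                      # 37.2539
#' predict_min_input(111.3, 36.52)              # ~37.34
#' @export
predict_max_input <- function(score1, score2, model = max_input_model(),
                              correct_offset = FALSE) {
  stopifnot(all(is.finite(score1)), all(is.finite(score2)))
  evaluate_linear_model(list(score1 = score1, score2 = score2),
                        model, correct_offset)
}

#' @rdname predict_max_input
#' @param hr_smoothed Smoothed heart rate (beats/min).
#' @param t_ins_scapula Insulated scapula skin temperature (degC).
#' @export
predict_min_input <- function(hr_smoothed, t_ins_scapula,
                              model = min_input_model(),
                              correct_offset = FALSE) {
  if (!all(is.finite(hr_smoothed)) || !all(is.finite(t_ins_scapula))) {
    stop("non-finite inputs to predict_min_input", call. = FALSE)
  }
  if (any(hr_smoothed < 30 | hr_smoothed > 230)) {
    warning("heart rate outside the physiologic range 30-230 beats/min")
  }
  if (any(t_ins_scapula < 25 | t_ins_scapula > 42)) {
    warning("insulated scapula temperature outside the physiologic range 25-42 degC")
  }
  evaluate_linear_model(list(heart_rate = hr_smoothed,
                             insulated_skin_temp_scapula = t_ins_scapula),
                        model, correct_offset)
}

#' Per-sample prediction over a preprocessed session
#'
#' Evaluates a prediction model at every time point of a preprocessed
#' session (smoothing already applied). For the Max-Input path the
#' component scores are computed first from the 18 predictor channels;
#' predictions are missing wherever any required input is missing.
#'
#' @param record A preprocessed [session_record()].
#' @param model `"max_input"`, `"min_input"`, a
#'   [linear_prediction_model()], or an external model over channel names.
#' @param correct_offset Subtract the model's systematic offset?
#' @param score_model Score model for the Max-Input path.
#' @return Numeric vector of predicted rectal temperature per sample.
#' @export
predict_session <- function(record, model = "min_input", correct_offset = TRUE,
                            score_model = component_score_model()) {
  if (is.character(model)) {
    model <- switch(match.arg(model, c("max_input", "min_input")),
                    max_input = max_input_model(),
                    min_input = min_input_model())
  }
  stopifnot(inherits(model, "linear_prediction_model"))
  uses_scores <- any(names(model$terms) %in% c("score1", "score2"))
  if (uses_scores) {
    need <- score_model$table$channel
  } else {
    need <- names(model$terms)
  }
  absent <- setdiff(need, names(record$channels))
  if (length(absent)) stop("model requires absent channel(s): ",
                           paste(absent, collapse = ", "), call. = FALSE)
  ok <- rowSums(is.na(record$channels[need])) == 0
  out <- rep(NA_real_, session_length(record))
  if (!any(ok)) return(out)
  if (uses_scores) {
    sc <- component_scores(record$channels[ok, need, drop = FALSE], score_model)
    inputs <- list(score1 = sc$score1, score2 = sc$score2)
  } else {
    inputs <- as.list(record$channels[ok, need, drop = FALSE])
  }
  out[ok] <- evaluate_linear_model(inputs, model, correct_offset)
  out
}
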