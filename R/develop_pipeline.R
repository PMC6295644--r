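#' End-to-end model development on a cohort
#'
#' Runs the full development procedure on a cohort of sessions:
#' participant-level development/validation split; preprocessing and
#' complete-case filtering of each session; outlier screening on the
#' pooled development rows; PCA with varimax rotation and a forced-entry
#' component regression (the cohort's own Max-Input analogue);
#' collinearity pruning and backward stepwise reduction to the minimal
#' admissible raw-parameter equation (the Min-Input analogue); and
#' validation of both refitted models on the held-out participants,
#' including the systematic offset computed over the validation pool.
#'
#' @param records List of [session_record()]s (or of `list(record, ...)`
#'   entries as returned by [simulate_cohort()]).
#' @param config A [development_config()].
#' @param pre_config A [preprocess_config()].
#' @param screen Apply outlier screening to the development pool?
#' @return A `development_result`: `split`, `pca`, `max_fit`, `max_model`
#'   (with validation offset), `score_model`, `pruned`, `reduction`,
#'   `min_fit`, `min_model`, `validation` (list of
#'   [validation_metrics()] reports per model), `n_development`,
#'   `n_validation`.
#' @export
develop_models <- function(records, config = development_config(),
                           pre_config = preprocess_config(), screen = TRUE) {
  records <- lapply(records, function(r) if (inherits(r, "session_record")) r else r$record)
  predictors <- predictor_channels()
  pooled <- lapply(records, function(r) {
    p <- preprocess_session(r, pre_config)
    cc <- complete_case_filter(p, c(predictors, "rectal_temp"))$record
    cbind(data.frame(participant_id = rep(cc$participant_id,
                                          session_length(cc))),
          cc$channels[c(predictors, "rectal_temp")])
  })
  pooled <- do.call(rbind, pooled)

  split <- split_participants(unique(pooled$participant_id), config$split_seed)
  dev <- pooled[pooled$participant_id %in% split$development, ]
  val <- pooled[pooled$participant_id %in% split$validation, ]

  X_dev <- dev[predictors]
  y_dev <- dev$rectal_temp
  if (screen) {
    rep_out <- flag_outliers(X_dev, y_dev, resid_limit = config$resid_limit)
    X_dev <- X_dev[rep_out$keep, , drop = FALSE]
    y_dev <- y_dev[rep_out$keep]
  } else {
    rep_out <- NULL
  }

  pca <- fit_pca_varimax(X_dev, config)
  score_model <- as_component_score_model(pca)
  sc_dev <- component_scores(X_dev, score_model)
  max_fit <- regression_forced_entry(data.frame(score1 = sc_dev$score1,
                                                score2 = sc_dev$score2), y_dev)
  max_model <- linear_prediction_model("max_input_refit", max_fit$coefficients,
                                       max_fit$intercept)

  pruned <- prune_collinear(X_dev, y_dev, config)
  reduction <- stepwise_reduce(X_dev[pruned], y_dev, config)
  min_fit <- reduction$final
  min_model <- linear_prediction_model("min_input_refit", min_fit$coefficients,
                                       min_fit$intercept)

  # validation: raw predictions, offset over the validation pool, metrics
  validate <- function(model, scores) {
    inputs <- if (scores) {
      sc <- component_scores(val[predictors], score_model)
      list(score1 = sc$score1, score2 = sc$score2)
    } else {
      as.list(val[names(model$terms)])
    }
    raw <- evaluate_linear_model(inputs, model)
    offset <- mean(raw - val$rectal_temp)
    model$offset <- offset
    list(model = model,
         report = validation_metrics(val$rectal_temp, raw - offset))
  }
  vmax <- validate(max_model, scores = TRUE)
  vmin <- validate(min_model, scores = FALSE)

  structure(list(split = split, screening = rep_out, pca = pca,
                 score_model = score_model,
                 max_fit = max_fit, max_model = vmax$model,
                 pruned = pruned, reduction = reduction,
                 min_fit = min_fit, min_model = vmin$model,
                 validation = list(max_input = vmax$report,
                                   min_input = vmin$report),
                 n_development = nrow(X_dev), n_validation = nrow(val)),
            class = "development_result")
}

#' @export
print.development_result <- function(x, ...) {
  cat(sprintf("<development_result: %d dev / %d val rows; %d component(s); pruned to %d, reduced to %d term(s)>\n",
              x$n_development, x$n_validation, x$pca$n_components,
              length(x$pruned), x$min_fit$k))
  cat("  min-input terms:", paste(names(x$min_model$terms), collapse = ", "), "\n")
  cat(sprintf("  validation SEE: max %.3f / min %.3f degC\n",
              x$validation$max_input$see, x$validation$min_input$see))
  invisible(x)
}

#' Serialize developed models
#'
#' Writes/reads the component-score model and the linear prediction
#' models of a development run as a versioned JSON file consumable by
#' the prediction path.
#'
#' @param result A `development_result` (or a list with `score_model`,
#'   `max_model`, `min_model`).
#' @param path JSON file path.
#' @export
write_model_file <- function(result, path) {
  models <- list(result$max_model, result$min_model)
  names(models) <- vapply(models, `[[`, character(1), "name")
  payload <- list(
    format = "coretemp-model/1",
    score_model = result$score_model$table,
    models = lapply(models, function(m) {
      list(terms = as.list(m$terms), intercept = m$intercept, offset = m$offset)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_model_file
#' @return `read_model_file` returns a list with `score_model` and a
#'   named list of `models`.
#' @export
read_model_file <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "coretemp-model/1")) {
    stop("not a coretemp model file: ", path, call. = FALSE)
  }
  models <- lapply(names(payload$models), function(nm) {
    m <- payload$models[[nm]]
    linear_prediction_model(nm, unlist(m$terms), m$intercept, m$offset)
  })
  names(models) <- names(payload$models)
  list(score_model = component_score_model(as.data.frame(payload$score_model)),
       models = models)
}
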