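#' Development configuration
#'
#' Thresholds of the model-development procedure: the Kaiser eigenvalue
#' criterion for retaining principal components, the pairwise
#' correlation limit above which one of a pair of predictors is pruned,
#' the backward-reduction stopping rules (SEE must stay below
#' `see_limit_c` and the cumulative adjusted-R-squared drop relative to
#' the full pruned model must not exceed `r2adj_drop_limit`), the
#' studentized-residual cutoff for screening, and the entry/removal
#' p-values of the stepwise regression used inside collinearity pruning.
#'
#' @param kaiser_eigenvalue_min Retain components with eigenvalue above
#'   this (default 1).
#' @param collinearity_r Pairwise |r| threshold (default 0.9).
#' @param see_limit_c SEE ceiling in degC (default 0.5).
#' @param r2adj_drop_limit Maximum cumulative adjusted-R-squared drop
#'   (default 0.05).
#' @param resid_limit Studentized-residual cutoff (default 3).
#' @param stepwise_p_enter,stepwise_p_remove Stepwise thresholds
#'   (defaults 0.05 / 0.10).
#' @param split_seed Seed of the participant split.
#' @return A `development_config` list.
#' @export
development_config <- function(kaiser_eigenvalue_min = 1.0,
                               collinearity_r = 0.9,
                               see_limit_c = 0.5,
                               r2adj_drop_limit = 0.05,
                               resid_limit = 3,
                               stepwise_p_enter = 0.05,
                               stepwise_p_remove = 0.10,
                               split_seed = 1L) {
  stopifnot(collinearity_r > 0, collinearity_r < 1, see_limit_c > 0,
            r2adj_drop_limit >= 0, resid_limit > 0,
            stepwise_p_enter <= stepwise_p_remove)
  structure(list(kaiser_eigenvalue_min = kaiser_eigenvalue_min,
                 collinearity_r = collinearity_r,
                 see_limit_c = see_limit_c,
                 r2adj_drop_limit = r2adj_drop_limit,
                 resid_limit = resid_limit,
                 stepwise_p_enter = stepwise_p_enter,
                 stepwise_p_remove = stepwise_p_remove,
                 split_seed = as.integer(split_seed)),
            class = "development_config")
}

#' Participant-level development/validation split
#'
#' Randomly partitions participants into a development and a validation
#' group of near-even size (e.g. 7/6 for 13 participants); both sessions
#' of a participant stay in the same group.
#'
#' @param participants Character vector of participant ids (deduplicated).
#' @param seed Integer seed; the same seed reproduces the same split.
#' @return List with `development` and `validation` id vectors and the
#'   `seed` used.
#' @export
split_participants <- function(participants, seed = 1L) {
  ids <- unique(as.character(participants))
  if (length(ids) < 2) stop("need at least 2 participants to split", call. = FALSE)
  n_dev <- ceiling(length(ids) / 2)
  old <- .Random.seed_exists()
  set.seed(seed)
  dev_ids <- sort(sample(ids, n_dev))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  list(development = dev_ids,
       validation = sort(setdiff(ids, dev_ids)),
       seed = as.integer(seed))
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' KMO compares observed correlations with partial correlations: with
#' off-diagonal correlations r_jk and partial correlations q_jk (from
#' the anti-image of the correlation matrix),
#' overall KMO = sum r^2 / (sum r^2 + sum q^2); the per-item statistic
#' restricts the sums to one row.
#'
#' @param x Numeric data matrix/frame (rows = observations), or a
#'   correlation matrix (square, unit diagonal).
#' @return List with `overall` and named `per_item` values.
#' @export
kmo_statistic <- function(x) {
  R <- as_correlation(x)
  p <- ncol(R)
  Rinv <- tryCatch(solve(R), error = function(e) {
    stop("singular correlation matrix: KMO undefined", call. = FALSE)
  })
  Q <- -stats::cov2cor(Rinv)  # partial correlations (off-diagonal)
  diag(Q) <- 0
  diag(R) <- 0
  r2 <- R^2
  q2 <- Q^2
  overall <- sum(r2) / (sum(r2) + sum(q2))
  per_item <- rowSums(r2) / (rowSums(r2) + rowSums(q2))
  names(per_item) <- colnames(x) %||% paste0("V", seq_len(p))
  list(overall = overall, per_item = per_item)
}

as_correlation <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == ncol(x) && all(abs(diag(x) - 1) < 1e-12) &&
      max(abs(x - t(x))) < 1e-12) {
    return(x)
  }
  stats::cor(x)
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix differs from identity:
#' chi2 = -(n - 1 - (2p + 5)/6) * ln det(R), df = p(p - 1)/2.
#'
#' @param x Data matrix/frame with n rows and p columns (n > p).
#' @return List with `chisq`, `df`, `p_value`, `n`.
#' @export
bartlett_sphericity <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  stopifnot(n > p)
  R <- stats::cor(x)
  detR <- det(R)
  if (!is.finite(detR) || detR <= 0) {
    stop("correlation matrix not positive definite: Bartlett test undefined",
         call. = FALSE)
  }
  chisq <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE), n = n)
}

#' PCA with varimax rotation and regression-method score coefficients
#'
#' Principal component analysis on the correlation matrix of the
#' predictors; components with eigenvalue above the Kaiser criterion
#' are retained and their loading matrix is varimax-rotated (Kaiser
#' normalization). Score coefficients follow the regression method,
#' W = R^-1 L_rot, so that scores computed on the (standardized)
#' development data have unit variance per component and near-zero
#' inter-component correlation. Sign convention: each component's
#' largest-magnitude loading is positive.
#'
#' @param x Complete-case data matrix/frame, n rows > p columns.
#' @param config A [development_config()].
#' @return A `pca_result`: `n_components`, `loadings`, `score_coefficients`,
#'   `eigenvalues`, `cumulative_variance` (proportion explained by the
#'   retained components), `kmo`, `bartlett`, `means`, `sds`.
#' @export
fit_pca_varimax <- function(x, config = development_config()) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  stopifnot(n > p)
  if (anyNA(x)) stop("fit_pca_varimax requires complete cases", call. = FALSE)
  R <- stats::cor(x)
  eig <- eigen(R, symmetric = TRUE)
  keep <- which(eig$values > config$kaiser_eigenvalue_min)
  if (!length(keep)) stop("no component exceeds the Kaiser criterion", call. = FALSE)
  m <- max(keep)
  L <- eig$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(eig$values[seq_len(m)]), m)
  rot <- if (m > 1) {
    vm <- stats::varimax(L, normalize = TRUE, eps = 1e-6)
    L %*% vm$rotmat
  } else L
  # sign convention: dominant loading of each component positive
  for (j in seq_len(m)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  W <- solve(R, rot)
  cn <- colnames(x) %||% paste0("V", seq_len(p))
  dimnames(rot) <- dimnames(W) <- list(cn, paste0("component", seq_len(m)))
  structure(list(n_components = m,
                 loadings = rot,
                 score_coefficients = W,
                 eigenvalues = eig$values,
                 cumulative_variance = sum(eig$values[seq_len(m)]) / p,
                 kmo = kmo_statistic(R),
                 bartlett = bartlett_sphericity(x),
                 means = colMeans(x),
                 sds = apply(x, 2, stats::sd)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result: %d component(s), %.1f%% variance; KMO %.2f; Bartlett chi2(%d) = %.2f>\n",
              x$n_components, 100 * x$cumulative_variance, x$kmo$overall,
              x$bartlett$df, x$bartlett$chisq))
  invisible(x)
}

#' @rdname fit_pca_varimax
#' @param pca A `pca_result`.
#' @return `as_component_score_model` converts a two-component
#'   `pca_result` into a [component_score_model()] usable for prediction.
#' @export
as_component_score_model <- function(pca) {
  stopifnot(inherits(pca, "pca_result"))
  if (pca$n_components != 2) {
    stop("component-score prediction expects exactly 2 retained components, got ",
         pca$n_components, call. = FALSE)
  }
  component_score_model(data.frame(channel = rownames(pca$score_coefficients),
                                   coef1 = pca$score_coefficients[, 1],
                                   coef2 = pca$score_coefficients[, 2],
                                   mean = pca$means, sd = pca$sds,
                                   stringsAsFactors = FALSE))
}

#' Forced-entry multiple linear regression
#'
#' Ordinary least squares of the response on all supplied regressors,
#' reporting per-term standardized beta (coefficients of the z-scored
#' fit), t and two-sided p, SEE = sqrt(SS_res / (n - k - 1)), R-squared
#' and adjusted R-squared.
#'
#' @param X Data frame/matrix of regressors (complete).
#' @param y Response vector.
#' @return A `regression_fit` with `coefficients`, `intercept`, `terms`
#'   (data frame: estimate, std_beta, t, p), `see`, `r_squared`,
#'   `r_squared_adj`, `n`, and the underlying `lm` fit.
#' @export
regression_forced_entry <- function(X, y) {
  X <- as.data.frame(X)
  stopifnot(nrow(X) == length(y))
  if (anyNA(X) || anyNA(y)) stop("regression requires complete cases", call. = FALSE)
  dat <- cbind(X, .y = y)
  fit <- stats::lm(.y ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; drop collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  co <- sm$coefficients
  terms <- setdiff(rownames(co), "(Intercept)")
  sx <- vapply(X, stats::sd, numeric(1))
  names(sx) <- names(X)
  # lm backtick-quotes non-syntactic names; map back to the originals
  clean <- gsub("^`|`$", "", terms)
  std_beta <- co[terms, "Estimate"] * sx[clean] / stats::sd(y)
  k <- length(terms)
  n <- nrow(X)
  structure(list(coefficients = stats::setNames(co[terms, "Estimate"], clean),
                 intercept = co["(Intercept)", "Estimate"],
                 terms = data.frame(term = clean,
                                    estimate = co[terms, "Estimate"],
                                    std_beta = unname(std_beta),
                                    t = co[terms, "t value"],
                                    p = co[terms, "Pr(>|t|)"],
                                    row.names = NULL),
                 see = sm$sigma,
                 r_squared = sm$r.squared,
                 r_squared_adj = sm$adj.r.squared,
                 n = n, k = k, lm = fit),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit: %d term(s), n = %d, SEE = %.4f, R2adj = %.4f>\n",
              x$k, x$n, x$see, x$r_squared_adj))
  print(x$terms, digits = 3)
  invisible(x)
}

# SPSS-style p-value stepwise selection (forward entry with backward
# removal after each entry). Returns the selected terms and, for ranking,
# a p-value per candidate: its model p if selected, else its
# p-if-entered into the final model. Ties break toward larger |t|.
stepwise_select <- function(X, y, p_enter = 0.05, p_remove = 0.10) {
  X <- as.data.frame(X)
  candidates <- names(X)
  selected <- character()
  # a variable collinear with the current model cannot enter: p = 1, |t| = 0
  try_entry <- function(v) {
    fit <- tryCatch(regression_forced_entry(X[c(selected, v)], y),
                    error = function(e) NULL)
    if (is.null(fit)) return(c(p = 1, t = 0))
    row <- fit$terms[fit$terms$term == v, ]
    c(p = row$p, t = abs(row$t))
  }
  repeat {
    outside <- setdiff(candidates, selected)
    if (!length(outside)) break
    entry <- vapply(outside, try_entry, numeric(2))
    best <- order(entry["p", ], -entry["t", ])[1]
    if (entry["p", best] >= p_enter) break
    selected <- c(selected, outside[best])
    # backward pass
    repeat {
      if (length(selected) < 2) break
      fit <- regression_forced_entry(X[selected], y)
      worst <- order(-fit$terms$p, abs(fit$terms$t))[1]
      if (fit$terms$p[worst] <= p_remove) break
      selected <- setdiff(selected, fit$terms$term[worst])
    }
  }
  pvals <- stats::setNames(rep(NA_real_, length(candidates)), candidates)
  tvals <- pvals
  if (length(selected)) {
    fit <- regression_forced_entry(X[selected], y)
    pvals[fit$terms$term] <- fit$terms$p
    tvals[fit$terms$term] <- abs(fit$terms$t)
  }
  for (v in setdiff(candidates, selected)) {
    pt <- try_entry(v)
    pvals[v] <- pt[["p"]]
    tvals[v] <- pt[["t"]]
  }
  list(selected = selected, p = pvals, t = tvals)
}

#' Collinearity pruning
#'
#' Repeatedly finds the predictor pair with the largest pairwise
#' correlation above the threshold and drops one member, keeping the
#' member with the higher significance (smaller p-value; ties broken by
#' larger |t|) in a stepwise regression of the response on the current
#' candidate set. Stops when no pair exceeds the threshold.
#'
#' @param X Complete data frame of predictors.
#' @param y Response vector.
#' @param config A [development_config()].
#' @return Character vector of retained predictor names (original order).
#' @export
prune_collinear <- function(X, y, config = development_config()) {
  X <- as.data.frame(X)
  retained <- names(X)
  repeat {
    R <- abs(stats::cor(X[retained]))
    diag(R) <- 0
    if (max(R) <= config$collinearity_r) break
    idx <- which(R == max(R), arr.ind = TRUE)[1, ]
    a <- retained[idx[1]]; b <- retained[idx[2]]
    sw <- stepwise_select(X[retained], y,
                          config$stepwise_p_enter, config$stepwise_p_remove)
    # both selected or both outside: compare their p (then |t|) directly
    rank_ab <- order(sw$p[c(a, b)], -sw$t[c(a, b)])
    drop_var <- c(a, b)[rank_ab[2]]
    retained <- setdiff(retained, drop_var)
    if (length(retained) == 1) break
  }
  retained
}

#' Backward stepwise reduction
#'
#' Starting from the forced-entry fit on all retained predictors, drops
#' the term with the smallest |standardized beta| one at a time,
#' refitting after each removal, for as long as the refit still
#' satisfies SEE < `see_limit_c` and the cumulative adjusted-R-squared
#' drop from the full model does not exceed `r2adj_drop_limit`. Removed
#' terms are never re-entered.
#'
#' @param X Complete data frame of (pruned) predictors.
#' @param y Response vector.
#' @param config A [development_config()].
#' @return List with `trajectory` (list of `regression_fit`s, largest
#'   model first) and `final` (the last admissible fit).
#' @export
stepwise_reduce <- function(X, y, config = development_config()) {
  X <- as.data.frame(X)
  stopifnot(ncol(X) >= 2)
  fit <- regression_forced_entry(X, y)
  if (fit$see >= config$see_limit_c) {
    warning("full pruned model already violates the SEE limit")
  }
  r2adj_full <- fit$r_squared_adj
  trajectory <- list(fit)
  terms <- names(X)
  while (length(terms) > 1) {
    drop_var <- fit$terms$term[which.min(abs(fit$terms$std_beta))]
    cand_terms <- setdiff(terms, drop_var)
    cand <- regression_forced_entry(X[cand_terms], y)
    if (cand$see >= config$see_limit_c ||
        (r2adj_full - cand$r_squared_adj) > config$r2adj_drop_limit) {
      break
    }
    terms <- cand_terms
    fit <- cand
    trajectory <- c(trajectory, list(fit))
  }
  list(trajectory = trajectory, final = fit)
}

#' Validation metrics
#'
#' Quantifies agreement between measured and predicted rectal
#' temperature. In the default `"regression"` mode the measured series
#' is regressed on the predicted series and SEE = sqrt(SS_res/(n - 2)),
#' with adjusted R-squared 1 - (1 - R2)(n - 1)/(n - 2). In
#' `"difference"` mode SEE is instead the RMSE of (predicted -
#' measured). The mean offset (predicted - measured) is always reported.
#'
#' @param measured,predicted Paired numeric vectors; pairs with missing
#'   values are dropped (length >= 3 after dropping).
#' @param mode `"regression"` (default) or `"difference"`.
#' @return A `validation_report`: `see`, `r_squared_adj`, `mean_offset`,
#'   `n`, `mode`.
#' @export
validation_metrics <- function(measured, predicted,
                               mode = c("regression", "difference")) {
  mode <- match.arg(mode)
  stopifnot(length(measured) == length(predicted))
  ok <- !is.na(measured) & !is.na(predicted)
  measured <- measured[ok]; predicted <- predicted[ok]
  n <- length(measured)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(predicted) == 0) {
    stop("predicted series has zero variance: correspondence undefined",
         call. = FALSE)
  }
  fit <- stats::lm(measured ~ predicted)
  r2 <- summary(fit)$r.squared
  see <- if (mode == "regression") {
    sqrt(sum(stats::residuals(fit)^2) / (n - 2))
  } else {
    sqrt(mean((predicted - measured)^2))
  }
  structure(list(see = see,
                 r_squared_adj = 1 - (1 - r2) * (n - 1) / (n - 2),
                 mean_offset = mean(predicted - measured),
                 n = n, mode = mode),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report (%s mode): SEE = %.3f degC, R2adj = %.3f, offset = %+.3f degC, n = %d>\n",
              x$mode, x$see, x$r_squared_adj, x$mean_offset, x$n))
  invisible(x)
}
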