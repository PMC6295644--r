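#' Chi-squared critical value
#'
#' Upper-tail critical value of the chi-squared distribution, used to
#' threshold squared Mahalanobis distances: with 18 predictors and a
#' 0.001 tail this gives the screening cutoff 42.31.
#'
#' @param df Degrees of freedom (>= 1).
#' @param p Upper-tail probability in (0, 1).
#' @return The value x with P(X > x) = p for X ~ chi-squared(df).
#' @examples
#' chi2_critical_value(18, 0.001)  # 42.31...
#' @export
chi2_critical_value <- function(df, p) {
  stopifnot(df >= 1, p > 0, p < 1)
  stats::qchisq(p, df = df, lower.tail = FALSE)
}

#' Squared Mahalanobis distances
#'
#' Squared Mahalanobis distance of each row from the sample mean under
#' the sample covariance (denominator n - 1):
#' d2_i = (x_i - xbar)' S^-1 (x_i - xbar).
#'
#' @param x Numeric matrix or data frame, n rows > p columns, complete.
#' @return Numeric vector of length n.
#' @export
mahalanobis_d2 <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("mahalanobis_d2 requires complete cases", call. = FALSE)
  n <- nrow(x); p <- ncol(x)
  if (n <= p) stop("need more rows than columns (n > p)", call. = FALSE)
  ctr <- sweep(x, 2, colMeans(x))
  S <- crossprod(ctr) / (n - 1)
  singular <- function() {
    cn <- colnames(x) %||% paste0("V", seq_len(p))
    stop("singular sample covariance; check for collinear columns among: ",
         paste(cn, collapse = ", "), call. = FALSE)
  }
  R <- tryCatch(chol(S), error = function(e) singular())
  if (any(diag(R) <= sqrt(.Machine$double.eps) * max(diag(R)))) singular()
  z <- backsolve(R, t(ctr), transpose = TRUE)
  colSums(z^2)
}

#' Multivariate and residual outlier screening
#'
#' One-pass outlier removal on complete-case data: first, time points
#' whose squared Mahalanobis distance over the predictor matrix exceeds
#' the chi-squared critical value for `df = ncol(x)` at tail `p` are
#' removed; then a working regression of the response on the predictors
#' is fitted to the survivors and points with internally studentized
#' residuals outside `[-resid_limit, resid_limit]` are removed.
#'
#' By default the working regression is the component regression: the
#' two component scores of the shipped score model are the regressors.
#' Set `working = "raw"` to regress on the raw predictors instead.
#'
#' @param x Complete predictor matrix/data frame (columns = channels).
#' @param y Response vector (rectal temperature), same length as rows.
#' @param p Chi-squared upper-tail probability (default 0.001).
#' @param resid_limit Absolute studentized-residual cutoff (default 3).
#' @param working `"component"` (default; requires the 18 predictor
#'   columns) or `"raw"`.
#' @param score_model Component-score model for the component working
#'   regression (default: the shipped model).
#' @return An `outlier_report` list: `mahalanobis_d2`, `threshold`,
#'   `removed_multivariate`, `removed_residual` (row-index sets, disjoint),
#'   `keep` (logical vector).
#' @export
flag_outliers <- function(x, y, p = 0.001, resid_limit = 3,
                          working = c("component", "raw"),
                          score_model = component_score_model()) {
  working <- match.arg(working)
  x <- as.data.frame(x)
  stopifnot(length(y) == nrow(x))
  if (anyNA(x) || anyNA(y)) stop("flag_outliers requires complete cases", call. = FALSE)
  d2 <- mahalanobis_d2(x)
  threshold <- chi2_critical_value(ncol(x), p)
  removed_mv <- which(d2 > threshold)
  keep <- d2 <= threshold

  X <- if (working == "component") {
    sc <- component_scores(x, score_model)
    data.frame(score1 = sc$score1, score2 = sc$score2)
  } else {
    x
  }
  fit <- stats::lm(y ~ ., data = cbind(X, y = y)[keep, , drop = FALSE])
  rs <- stats::rstandard(fit)
  removed_res <- which(keep)[is.finite(rs) & abs(rs) > resid_limit]
  keep[removed_res] <- FALSE
  structure(list(mahalanobis_d2 = d2, threshold = threshold,
                 removed_multivariate = removed_mv,
                 removed_residual = removed_res,
                 keep = keep),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report: %d multivariate (d2 > %.2f), %d residual removed; %d/%d kept>\n",
              length(x$removed_multivariate), x$threshold,
              length(x$removed_residual), sum(x$keep), length(x$keep)))
  invisible(x)
}

#' @rdname flag_outliers
#' @param report An `outlier_report`.
#' @param path CSV output path.
#' @export
write_outlier_report <- function(report, path) {
  df <- data.frame(index = seq_along(report$keep),
                   mahalanobis_d2 = report$mahalanobis_d2,
                   removed_multivariate = seq_along(report$keep) %in% report$removed_multivariate,
                   removed_residual = seq_along(report$keep) %in% report$removed_residual,
                   keep = report$keep)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
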