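test_that("participant split is even, participant-level and seed-reproducible", {
  ids <- sprintf("P%02d", 1:13)
  sp <- split_participants(ids, seed = 4)
  expect_length(sp$development, 7)
  expect_length(sp$validation, 6)
  expect_setequal(c(sp$development, sp$validation), ids)
  expect_identical(sp, split_participants(ids, seed = 4))
  expect_false(identical(sp$development, split_participants(ids, seed = 5)$development))

  sp2 <- split_participants(c("a", "b"), seed = 1)
  expect_length(sp2$development, 1)
  expect_length(sp2$validation, 1)
  expect_error(split_participants("solo"), "at least 2")
})

test_that("KMO matches a from-scratch partial-correlation oracle and is high for factor-driven data", {
  set.seed(41)
  x <- two_factor_data(2000, p = 6, loading = 0.9)
  got <- kmo_statistic(x)
  expect_gt(got$overall, 0.5)

  # oracle: partial correlation of (i, j) given the rest via regression residuals
  p <- ncol(x)
  partial <- matrix(0, p, p)
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    others <- x[, -c(i, j), drop = FALSE]
    ri <- resid(lm(x[, i] ~ others))
    rj <- resid(lm(x[, j] ~ others))
    partial[i, j] <- partial[j, i] <- cor(ri, rj)
  }
  R <- cor(x); diag(R) <- 0
  overall_oracle <- sum(R^2) / (sum(R^2) + sum(partial^2))
  expect_equal(got$overall, overall_oracle, tolerance = 1e-8)
  item_oracle <- rowSums(R^2) / (rowSums(R^2) + rowSums(partial^2))
  expect_equal(unname(got$per_item), item_oracle, tolerance = 1e-8)
})

test_that("Bartlett sphericity follows the determinant formula with df = p(p-1)/2", {
  set.seed(42)
  x <- two_factor_data(500, p = 18, loading = 0.8)
  got <- bartlett_sphericity(x)
  expect_equal(got$df, 153)
  n <- nrow(x); p <- ncol(x)
  expect_equal(got$chisq, -(n - 1 - (2 * p + 5) / 6) * log(det(cor(x))),
               tolerance = 1e-10)
  expect_lt(got$p_value, 0.001)

  # exactly uncorrelated columns: chi-squared statistic is zero
  z <- qr.Q(qr(scale(matrix(rnorm(400 * 4), ncol = 4), scale = FALSE)))
  expect_equal(bartlett_sphericity(z)$chisq, 0, tolerance = 1e-8)
})

test_that("PCA retains exactly the two latent components and produces unit-variance uncorrelated scores", {
  set.seed(43)
  x <- two_factor_data(5000, p = 10, loading = 0.9)
  colnames(x) <- paste0("V", 1:10)
  res <- fit_pca_varimax(x)
  expect_equal(res$n_components, 2)
  expect_true(all(diff(res$eigenvalues) <= 1e-12))
  expect_gt(res$cumulative_variance, 0.7)

  # regression-method scores: unit variance, near-zero inter-correlation
  z <- scale(x)
  scores <- z %*% res$score_coefficients
  expect_equal(apply(scores, 2, var), c(component1 = 1, component2 = 1),
               tolerance = 0.02)
  expect_lt(abs(cor(scores)[1, 2]), 0.05)

  # varimax separates the two blocks; dominant loadings positive
  block <- apply(abs(res$loadings), 1, which.max)
  expect_equal(length(unique(block[1:5])), 1)
  expect_equal(length(unique(block[6:10])), 1)
  expect_true(all(apply(res$loadings, 2, max) > 0.7))
})

test_that("retained loadings reproduce the correlation matrix better as components are added", {
  set.seed(44)
  x <- two_factor_data(2000, p = 8, loading = 0.85)
  R <- cor(x)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  err <- sapply(c(1, 2, 4), function(m) {
    # threshold between the m-th and (m+1)-th eigenvalue retains m components
    kmin <- (ev[m] + ev[m + 1]) / 2
    res <- fit_pca_varimax(x, development_config(kaiser_eigenvalue_min = kmin))
    stopifnot(res$n_components == m)
    L <- res$loadings
    norm(R - L %*% t(L), "F")
  })
  expect_true(all(diff(err) < 0))
})

test_that("forced-entry regression recovers exact fits, generative coefficients and the normal-equations oracle", {
  set.seed(45)
  X <- data.frame(a = rnorm(50), b = rnorm(50))
  y0 <- 2 * X$a - X$b + 1
  fit0 <- suppressWarnings(regression_forced_entry(X, y0))  # exact fit
  expect_equal(fit0$r_squared, 1)
  expect_equal(fit0$see, 0, tolerance = 1e-10)

  n <- 5000
  hr <- runif(n, 60, 180)
  tins <- rnorm(n, 36.52, 1.35)
  y <- 0.0100 * hr + 0.0837 * tins + 33.1735 + rnorm(n, 0, 0.05)
  fit <- regression_forced_entry(data.frame(heart_rate = hr,
                                            insulated_skin_temp_scapula = tins), y)
  se <- summary(fit$lm)$coefficients[, "Std. Error"]
  expect_lt(abs(fit$coefficients[["heart_rate"]] - 0.0100),
            3 * se[["heart_rate"]])
  expect_lt(abs(fit$coefficients[["insulated_skin_temp_scapula"]] - 0.0837),
            3 * se[["insulated_skin_temp_scapula"]])
  expect_lt(abs(fit$intercept - 33.1735), 3 * se[["(Intercept)"]])

  X3 <- matrix(rnorm(300), ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
  yy <- rnorm(100)
  fit3 <- regression_forced_entry(X3, yy)
  beta_oracle <- solve(crossprod(cbind(1, X3)), crossprod(cbind(1, X3), yy))
  expect_equal(unname(c(fit3$intercept, fit3$coefficients)),
               as.numeric(beta_oracle), tolerance = 1e-8)

  expect_error(regression_forced_entry(cbind(X, a2 = X$a), y0), "rank-deficient")
})

test_that("standardized betas are invariant to affine rescaling of the inputs", {
  set.seed(46)
  X <- data.frame(u = rnorm(200), v = rnorm(200))
  y <- X$u - 2 * X$v + rnorm(200, 0, 0.5)
  f1 <- regression_forced_entry(X, y)
  f2 <- regression_forced_entry(data.frame(u = 100 * X$u + 5, v = X$v / 3 - 1), y)
  expect_equal(f1$terms$std_beta, f2$terms$std_beta, tolerance = 1e-10)
})

test_that("collinearity pruning keeps the more significant member of each correlated pair", {
  set.seed(47)
  X <- data.frame(a = rnorm(300), b = rnorm(300), c = rnorm(300))
  y <- X$a + rnorm(300, 0, 0.3)
  expect_equal(prune_collinear(X, y), c("a", "b", "c"))  # no pair above 0.9

  X$a2 <- X$a  # exact duplicate: r = 1
  kept <- prune_collinear(X, y)
  expect_length(intersect(c("a", "a2"), kept), 1)

  # signal carrier survives against a noisy shadow of itself
  X2 <- data.frame(sig = rnorm(300))
  X2$shadow <- X2$sig + rnorm(300, 0, 0.1)  # r ~ 0.995
  y2 <- X2$sig + rnorm(300, 0, 0.2)
  expect_true("sig" %in% prune_collinear(X2, y2))

  # exhaustive-oracle check at small p: repeatedly drop from the worst pair
  set.seed(48)
  f <- rnorm(400)
  X3 <- data.frame(p1 = f + rnorm(400, 0, 0.2), p2 = f + rnorm(400, 0, 0.2),
                   p3 = f + rnorm(400, 0, 0.2), p4 = rnorm(400))
  y3 <- f + rnorm(400, 0, 0.3)
  kept3 <- prune_collinear(X3, y3)
  R <- abs(cor(X3[kept3])); diag(R) <- 0
  expect_lte(max(R), 0.9)
  expect_true("p4" %in% kept3)
})

test_that("backward reduction drops the weakest standardized betas and respects its stopping rules", {
  set.seed(49)
  n <- 4000
  hr <- runif(n, 60, 180)
  tins <- rnorm(n, 36.52, 1.35)
  noise_cols <- matrix(rnorm(n * 5, 0, 1), ncol = 5)
  colnames(noise_cols) <- c("skin_temp_radial", "skin_temp_arm",
                            "skin_temp_forehead", "heat_flux_sternum",
                            "heat_flux_scapula")
  X <- data.frame(heart_rate = hr, insulated_skin_temp_scapula = tins,
                  noise_cols)
  y <- 0.0100 * hr + 0.0837 * tins + 33.1735 + rnorm(n, 0, 0.1)
  red <- stepwise_reduce(X, y)
  expect_setequal(names(red$final$coefficients),
                  c("heart_rate", "insulated_skin_temp_scapula"))
  expect_lt(red$final$see, 0.5)
  # trajectory shrinks by one term per step
  ks <- vapply(red$trajectory, function(f) f$k, numeric(1))
  expect_equal(ks, seq(7, 2))

  # already-admissible two-parameter input
  X2 <- X[c("heart_rate", "insulated_skin_temp_scapula")]
  red2 <- stepwise_reduce(X2, y)
  expect_lte(red2$final$k, 2)

  # zero tolerated drop: stops at the first measurable degradation
  red0 <- stepwise_reduce(X, y, development_config(r2adj_drop_limit = 0))
  expect_gte(red0$final$r_squared_adj,
             red$trajectory[[1]]$r_squared_adj - 1e-12)
})

test_that("validation metrics reproduce exact, offset and hand-computed cases", {
  x <- c(37.0, 37.2, 37.4, 37.6, 37.8)
  vm <- suppressWarnings(validation_metrics(x, x))  # exact fits below too
  expect_equal(vm$see, 0, tolerance = 1e-10)
  expect_equal(vm$r_squared_adj, 1)
  expect_equal(vm$mean_offset, 0)

  vm2 <- suppressWarnings(validation_metrics(x, x + 0.24))
  expect_equal(vm2$mean_offset, 0.24)
  expect_equal(vm2$see, 0, tolerance = 1e-10)

  # hand-computed simple regression on a fixed 5-point series
  meas <- c(37.1, 37.0, 37.4, 37.9, 38.2)
  pred <- c(37.0, 37.2, 37.5, 37.7, 38.0)
  sxx <- sum((pred - mean(pred))^2)
  sxy <- sum((pred - mean(pred)) * (meas - mean(meas)))
  b <- sxy / sxx; a <- mean(meas) - b * mean(pred)
  res <- meas - a - b * pred
  r2 <- 1 - sum(res^2) / sum((meas - mean(meas))^2)
  vm3 <- validation_metrics(meas, pred)
  expect_equal(vm3$see, sqrt(sum(res^2) / 3), tolerance = 1e-12)
  expect_equal(vm3$r_squared_adj, 1 - (1 - r2) * 4 / 3, tolerance = 1e-12)
  expect_equal(vm3$mean_offset, mean(pred - meas))

  # difference mode: SEE is the RMSE of the differences
  vmd <- validation_metrics(meas, pred, mode = "difference")
  expect_equal(vmd$see, sqrt(mean((pred - meas)^2)))
  expect_error(validation_metrics(x, rep(37, 5)), "zero variance")
  expect_error(validation_metrics(x[1:2], x[1:2] + 0.1), "at least 3")
})
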