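map_family <- function(family) {
  switch(match.arg(family, c("binary", "continuous")),
         binary = "binomial", continuous = "gaussian")
}

# vectorized univariable OLS Wald tests (intercept included)
univ_tests_gaussian <- function(x, y) {
  n <- nrow(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  sxy <- drop(crossprod(xc, yc))
  b <- unname(sxy / sxx)
  rss <- sum(yc^2) - b * unname(sxy)
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 / unname(sxx))
  tval <- b / se
  tibble(estimate = b, std_error = se, statistic = tval,
         p_value = 2 * stats::pt(-abs(tval), df = n - 2))
}

univ_tests_binomial <- function(x, y) {
  n <- nrow(x); p <- ncol(x)
  est <- se <- pv <- numeric(p)
  fell_back <- FALSE
  for (j in seq_len(p)) {
    xm <- cbind(1, x[, j])
    fit <- suppressWarnings(stats::glm.fit(xm, y, family = binomial()))
    sep <- !fit$converged || any(abs(fit$coefficients) > 15)
    if (sep) {
      # separation: score test at the null (prevalence-only model)
      fell_back <- TRUE
      pbar <- mean(y)
      xc <- x[, j] - mean(x[, j])
      u <- sum(xc * (y - pbar))
      v <- pbar * (1 - pbar) * sum(xc^2)
      zst <- u / sqrt(v)
      est[j] <- NA_real_; se[j] <- NA_real_
      pv[j] <- 2 * pnorm(-abs(zst))
    } else {
      # Wald z from the inverse information
      w <- fit$weights
      xtwx <- crossprod(xm * sqrt(w))
      vc <- solve(xtwx)
      est[j] <- fit$coefficients[2]
      se[j] <- sqrt(vc[2, 2])
      z <- est[j] / se[j]
      pv[j] <- 2 * pnorm(-abs(z))
    }
  }
  if (fell_back) warn("separation in univariable logistic fit(s); score test used")
  tibble(estimate = est, std_error = se, statistic = est / se, p_value = pv)
}

univ_tests <- function(x, y, family) {
  if (family == "binary") univ_tests_binomial(x, y)
  else univ_tests_gaussian(x, y)
}

#' Univariable screening with a Bonferroni threshold
#'
#' Fits one univariable model (with intercept) per variable and selects those
#' whose two-sided Wald p-value falls below the threshold; the default
#' threshold is the Bonferroni-adjusted 0.05/p, i.e. 5e-5 at p = 1000.
#' Logistic fits with separation fall back to a score test with a warning.
#'
#' @param data Covariate tibble/matrix (standardized).
#' @param y Outcome vector matching `family`.
#' @param family `"binary"` or `"continuous"`.
#' @param p_threshold Per-test p-value threshold; default `0.05 / ncol(data)`.
#' @return A `selection_result` (method `UNIV-BFN`) whose `stats` field holds
#'   the per-variable estimates and p-values.
#' @export
univ_screen <- function(data, y, family = c("binary", "continuous"),
                        p_threshold = NULL) {
  family <- match.arg(family)
  x <- as.matrix(data)
  if (is.null(p_threshold)) p_threshold <- 0.05 / ncol(x)
  st <- univ_tests(x, y, family)
  new_selection_result("UNIV-BFN", which(st$p_value < p_threshold),
                       p = ncol(x), variable_names = colnames(x),
                       tuning = list(p_threshold = p_threshold),
                       stats = st)
}

#' Cross-validated lasso / elastic net selection
#'
#' Solves the elastic-net penalized likelihood over a lambda path for each
#' mixing value in `alpha_grid` (a grid of 1 alone is the lasso), picks the
#' `(alpha, lambda)` pair minimizing K-fold cross-validated prediction error
#' (deviance for binary outcomes, mean squared error for continuous), and
#' selects the variables with nonzero coefficients. `rule = "1se"` instead
#' takes, at the best alpha, the largest lambda whose CV error is within one
#' standard error of the minimum. The same fold assignment is shared across
#' the whole grid, and the intercept is never penalized.
#'
#' @inheritParams univ_screen
#' @param alpha_grid Elastic-net mixing values in (0, 1]; `1` is the lasso
#'   and `elnet_alpha_grid()` is the benchmark's 0.05-0.95 grid.
#' @param rule `"min"` or `"1se"`.
#' @param folds Number of CV folds.
#' @param seed Integer seed controlling the fold assignment.
#' @param nlambda,lambda_min_ratio Lambda path: `nlambda` log-spaced values
#'   down to `lambda_min_ratio` times the largest.
#' @return A `selection_result` with method `LASSO-MIN`/`LASSO-1SE` (single
#'   alpha of 1) or `ELNET-MIN`/`ELNET-1SE`; `path` holds the CV curve at the
#'   chosen alpha.
#' @export
fit_penalized_cv <- function(data, y, family = c("binary", "continuous"),
                             alpha_grid = 1, rule = c("min", "1se"),
                             folds = 10, seed = 1,
                             nlambda = 100, lambda_min_ratio = 0.001) {
  family <- match.arg(family)
  rule <- match.arg(rule)
  stopifnot(all(alpha_grid > 0), all(alpha_grid <= 1))
  x <- as.matrix(data)
  n <- nrow(x)
  set.seed(seed)
  foldid <- sample(rep(seq_len(folds), length.out = n))
  fits <- lapply(alpha_grid, function(a) {
    glmnet::cv.glmnet(x, y, family = map_family(family), alpha = a,
                      foldid = foldid, standardize = FALSE,
                      nlambda = nlambda, lambda.min.ratio = lambda_min_ratio,
                      type.measure = if (family == "binary") "deviance"
                                     else "mse")
  })
  best_cv <- vapply(fits, function(f) min(f$cvm), 0)
  ia <- which.min(best_cv)
  fit <- fits[[ia]]
  lam <- if (rule == "min") fit$lambda.min else fit$lambda.1se
  beta <- coef(fit, s = lam)[-1]
  lasso <- length(alpha_grid) == 1 && alpha_grid[1] == 1
  method <- paste0(if (lasso) "LASSO-" else "ELNET-",
                   if (rule == "min") "MIN" else "1SE")
  path <- tibble(lambda = fit$lambda, cv_error = fit$cvm, cv_se = fit$cvsd)
  new_selection_result(method, which(abs(beta) > 1e-10), p = ncol(x),
                       variable_names = colnames(x),
                       tuning = list(alpha = alpha_grid[ia], lambda = lam,
                                     lambda_min = fit$lambda.min,
                                     lambda_1se = fit$lambda.1se,
                                     intercept = as.numeric(coef(fit, s = lam))[1],
                                     rule = rule, folds = folds, seed = seed),
                       stats = tibble(estimate = as.numeric(beta)),
                       path = path)
}

#' Elastic-net alpha grid used by the benchmark
#' @return The numeric grid 0.05, 0.10, ..., 0.95.
#' @export
elnet_alpha_grid <- function() seq(0.05, 0.95, by = 0.05)

#' Check lasso / sparse-group-lasso stationarity conditions
#'
#' Verifies the Karush-Kuhn-Tucker conditions of the elastic-net objective at
#' a fitted coefficient vector: for zero coefficients the penalized score
#' must not exceed `lambda * alpha` (plus tolerance); for nonzero ones it
#' must match the subgradient.
#'
#' @param data,y,family Data the model was fitted to.
#' @param beta Fitted coefficient vector (no intercept).
#' @param intercept Fitted intercept.
#' @param lambda,alpha Penalty and mixing values.
#' @param tol Tolerance.
#' @return `TRUE` (invisibly) if the conditions hold, otherwise `FALSE` with
#'   attribute `max_violation`.
#' @export
check_kkt <- function(data, y, family, beta, intercept, lambda, alpha = 1,
                      tol = 1e-4) {
  x <- as.matrix(data)
  n <- nrow(x)
  eta <- intercept + drop(x %*% beta)
  resid <- if (family == "binary") y - stats::plogis(eta) else y - eta
  grad <- drop(crossprod(x, resid)) / n - lambda * (1 - alpha) * beta
  viol_zero <- pmax(abs(grad[beta == 0]) - lambda * alpha, 0)
  viol_nz <- abs(grad[beta != 0] - lambda * alpha * sign(beta[beta != 0]))
  mx <- max(c(0, viol_zero, viol_nz))
  out <- mx <= tol
  attr(out, "max_violation") <- mx
  out
}
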