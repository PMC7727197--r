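group_vector <- function(groups, p) {
  if (inherits(groups, "cluster_assignment")) groups <- groups$group
  groups <- as.integer(groups)
  stopifnot(length(groups) == p, !anyNA(groups))
  match(groups, sort(unique(groups)))  # contiguous 1..G
}

sgl_deviance <- function(eta, y, family) {
  if (family == "binary") {
    mu <- pmin(pmax(stats::plogis(eta), 1e-8), 1 - 1e-8)
    -2 * mean(y * log(mu) + (1 - y) * log(1 - mu))
  } else {
    mean((y - eta)^2)
  }
}

# columns of x must already be ordered so groups are contiguous blocks
sgl_path <- function(x, y, family, gstart, gend, gw, lambda, mix, tol,
                     maxit) {
  fit <- sgl_path_cpp(x, y, family == "binary", gstart, gend,
                      gw, lambda, mix, tol, as.integer(maxit))
  fit$b0 <- as.numeric(fit$b0)
  fit$lambda <- lambda
  fit
}

#' Sparse group lasso selection
#'
#' Native sparse group lasso: minimizes the model deviance plus
#' `lambda * ((1 - mix) * sum_g sqrt(p_g) ||beta_g||_2 + mix * ||beta||_1)`
#' by blockwise proximal gradient descent with group-level KKT screening and
#' warm starts along a decreasing lambda path. The group penalty zeroes whole
#' clusters of correlated variables while the elementwise penalty keeps
#' within-group sparsity; the intercept is unpenalized. Lambda is chosen by
#' K-fold cross-validation at the minimum prediction error.
#'
#' @inheritParams fit_penalized_cv
#' @param groups A [hierarchical_clusters()] / [bootstrap_clusters()]
#'   assignment, or an integer group label per column.
#' @param mix Mixing weight on the elementwise L1 penalty, in `[0, 1]`
#'   (1 is the plain lasso when all groups are singletons).
#' @param lambda Optional lambda values; by default a path of `nlambda`
#'   log-spaced values from the smallest lambda zeroing every group down to
#'   `lambda_min_ratio` times that (the 20-value, ratio-0.1 convention of
#'   standard sparse-group-lasso implementations; near-unpenalized logistic
#'   fits on near-duplicate variable blocks are unidentifiable, so the path
#'   stops well above zero).
#' @param cv If `FALSE`, skip cross-validation and return the fit at the
#'   smallest lambda supplied (requires `lambda`).
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @param maxit Maximum blockwise sweeps per lambda.
#' @param method_id Method tag recorded on the result.
#' @return A `selection_result`; `stats$estimate` holds the coefficients at
#'   the chosen lambda and `path` the CV curve.
#' @export
sgl_fit <- function(data, y, family = c("binary", "continuous"), groups,
                    mix = 0.95, lambda = NULL, folds = 10, seed = 1,
                    nlambda = 20, lambda_min_ratio = 0.1, cv = TRUE,
                    tol = 1e-7, maxit = 1e5, method_id = "HCLST-CORR-SGL") {
  family <- match.arg(family)
  x <- as.matrix(data)
  n <- nrow(x); p <- ncol(x)
  gvec <- group_vector(groups, p)
  # permute columns so every group is a contiguous block for the solver
  ord <- order(gvec)
  xo <- x[, ord, drop = FALSE]
  sizes <- as.numeric(table(gvec))
  gend <- as.integer(cumsum(sizes) - 1L)
  gstart <- as.integer(c(0L, head(gend, -1) + 1L))
  gw <- sqrt(sizes)
  if (is.null(lambda)) {
    lmax <- sgl_lambda_max_cpp(xo, y, family == "binary", gstart, gend, gw,
                               mix)
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = nlambda))
  } else {
    lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  }

  full <- sgl_path(xo, y, family, gstart, gend, gw, lambda, mix, tol, maxit)
  path <- NULL
  if (cv && length(lambda) > 1) {
    set.seed(seed)
    foldid <- sample(rep(seq_len(folds), length.out = n))
    errs <- matrix(NA_real_, folds, length(lambda))
    for (k in seq_len(folds)) {
      tr <- foldid != k
      fit_k <- sgl_path(xo[tr, , drop = FALSE], y[tr], family, gstart, gend,
                        gw, lambda, mix, tol, maxit)
      eta <- outer(rep(1, sum(!tr)), fit_k$b0) +
        xo[!tr, , drop = FALSE] %*% fit_k$beta
      errs[k, ] <- vapply(seq_along(lambda), function(il) {
        sgl_deviance(eta[, il], y[!tr], family)
      }, 0)
    }
    cvm <- colMeans(errs)
    cvsd <- apply(errs, 2, sd) / sqrt(folds)
    il <- which.min(cvm)
    path <- tibble(lambda = lambda, cv_error = cvm, cv_se = cvsd)
  } else {
    il <- length(lambda)  # smallest supplied lambda
  }
  beta <- numeric(p)
  beta[ord] <- full$beta[, il]  # back to the original column order
  new_selection_result(method_id, which(abs(beta) > 1e-10), p = p,
                       variable_names = colnames(x),
                       tuning = list(lambda = lambda[il], mix = mix,
                                     folds = if (cv) folds else NA_integer_,
                                     seed = seed,
                                     n_groups = length(gw),
                                     intercept = full$b0[il]),
                       stats = tibble(estimate = beta),
                       path = path)
}

#' Clustered sparse group lasso selection
#'
#' Composes variable clustering with the sparse group lasso: variables are
#' grouped by complete-linkage Spearman-distance clustering — either a
#' height cut at `cut_height` (members correlated above `1 - cut_height`) or
#' bootstrap-stability cluster detection — and the groups feed [sgl_fit()].
#'
#' @inheritParams sgl_fit
#' @param cluster_method `"corr_threshold"` or `"bootstrap"`.
#' @param cut_height Dendrogram height cut for the threshold variant.
#' @param B,stability_threshold Bootstrap variant settings.
#' @return A `selection_result` with method `HCLST-CORR-SGL` or
#'   `HCLST-BOOT-SGL`.
#' @export
hclst_sgl <- function(data, y, family = c("binary", "continuous"),
                      cluster_method = c("corr_threshold", "bootstrap"),
                      cut_height = 0.2, B = 1000, stability_threshold = 0.95,
                      mix = 0.95, folds = 10, seed = 1, ...) {
  family <- match.arg(family)
  cluster_method <- match.arg(cluster_method)
  if (cluster_method == "corr_threshold") {
    cl <- hierarchical_clusters(spearman_distance_matrix(data), cut_height)
    method_id <- "HCLST-CORR-SGL"
  } else {
    cl <- bootstrap_clusters(data, B = B,
                             stability_threshold = stability_threshold,
                             seed = seed)
    method_id <- "HCLST-BOOT-SGL"
  }
  out <- sgl_fit(data, y, family, groups = cl, mix = mix, folds = folds,
                 seed = seed, method_id = method_id, ...)
  out$tuning$cluster_method <- cluster_method
  out$tuning$n_groups <- attr(cl, "n_groups")
  out
}
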