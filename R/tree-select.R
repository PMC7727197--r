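#' Permutation variable importance with subsampling standard errors
#'
#' Fits a random forest (per-split candidate set of `floor(p/3)` variables
#' for continuous outcomes, `floor(sqrt(p))` for binary) or a bagged
#' ensemble (all `p` variables candidates at every split) and computes
#' out-of-bag permutation importance per variable. Standard errors come from
#' a delete-d jackknife over repeated fits on random subsamples of size
#' `n^subsample_exponent` drawn without replacement.
#'
#' @inheritParams univ_screen
#' @param mode `"forest"` or `"bagging"`.
#' @param n_trees Trees per ensemble (at least 250).
#' @param n_subsamples Number of subsample refits behind the jackknife SE.
#' @param subsample_exponent Subsample size exponent (size `n^0.75` by
#'   default).
#' @param seed Integer seed (fits use one thread, so results are
#'   reproducible).
#' @return A `vimp_estimate` tibble: `variable`, `importance`, `std_error`.
#' @export
rf_vimp <- function(data, y, family = c("binary", "continuous"),
                    mode = c("forest", "bagging"), n_trees = 1000,
                    n_subsamples = 100, subsample_exponent = 0.75, seed = 1) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  if (n_trees < 250) abort("n_trees must be at least 250")
  x <- as.matrix(data)
  n <- nrow(x); p <- ncol(x)
  m <- floor(n^subsample_exponent)
  if (m >= n || m < 10) abort("n too small for n^0.75 subsampling")
  mtry <- if (mode == "bagging") p
          else if (family == "binary") floor(sqrt(p)) else floor(p / 3)
  df <- data.frame(x)
  df$..y <- if (family == "binary") factor(y, levels = c(0, 1)) else y
  fit_one <- function(d, s) {
    ranger::ranger(dependent.variable.name = "..y", data = d,
                   num.trees = n_trees, mtry = mtry,
                   importance = "permutation", probability = FALSE,
                   num.threads = 1, seed = s)$variable.importance
  }
  imp <- fit_one(df, seed)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_subsamples)
  sub_imp <- matrix(NA_real_, n_subsamples, p)
  for (b in seq_len(n_subsamples)) {
    set.seed(sub_seeds[b])
    rows <- sample.int(n, m)
    sub_imp[b, ] <- fit_one(df[rows, , drop = FALSE], sub_seeds[b])
  }
  # delete-d jackknife with d = n - m
  vr <- (m / (n - m)) * colMeans(sweep(sub_imp, 2, imp)^2)
  out <- tibble(variable = colnames(x), importance = unname(imp),
                std_error = sqrt(vr))
  structure(out, class = c("vimp_estimate", class(out)),
            mode = mode, family = family, n_trees = n_trees, mtry = mtry,
            n_subsamples = n_subsamples, subsample_size = m, seed = seed)
}

#' Select variables whose VIMP confidence interval excludes zero
#'
#' Builds Bonferroni-style simultaneous normal-approximation confidence
#' intervals `importance +/- z * SE` at level `100 * (1 - alpha/p)%` (99.995%
#' at alpha = 0.05, p = 1000) and selects the variables whose lower bound is
#' positive.
#'
#' @param vimp A [rf_vimp()] result.
#' @param alpha Family-wise error rate before the `1/p` adjustment.
#' @param p Number of variables used in the adjustment (defaults to the
#'   number of rows of `vimp`).
#' @return A `selection_result` (method `RF` or `BAGGING`); `stats` carries
#'   the interval bounds.
#' @export
vimp_ci_select <- function(vimp, alpha = 0.05, p = nrow(vimp)) {
  stopifnot(inherits(vimp, "vimp_estimate"))
  level <- 1 - alpha / p
  z <- qnorm(1 - alpha / (2 * p))
  lower <- vimp$importance - z * vimp$std_error
  upper <- vimp$importance + z * vimp$std_error
  method <- if (attr(vimp, "mode") == "bagging") "BAGGING" else "RF"
  new_selection_result(method, which(lower > 0), p = nrow(vimp),
                       variable_names = vimp$variable,
                       tuning = list(alpha = alpha, ci_level = level,
                                     z = z, n_trees = attr(vimp, "n_trees")),
                       stats = tibble(importance = vimp$importance,
                                      std_error = vimp$std_error,
                                      ci_lower = lower, ci_upper = upper))
}
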