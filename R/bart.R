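#' Fit BART and record variable inclusion proportions
#'
#' Compact Bayesian additive regression trees sampler
#' (Metropolis-within-Gibbs backfitting over a sum-of-trees model with the
#' standard tree-depth, normal-leaf and inverse-chi-squared noise priors;
#' probit augmentation for binary outcomes). A variable's inclusion
#' proportion in a posterior draw is its share of all splitting rules across
#' the ensemble; draws with no splits count as uniform `1/p`. Small
#' ensembles (20 trees) sharpen the proportions for variable selection.
#'
#' @inheritParams univ_screen
#' @param n_trees Trees in the ensemble.
#' @param n_burn,n_post Burn-in and kept posterior draws.
#' @param k Leaf-prior shrinkage (larger shrinks leaf values harder).
#' @param base,power Tree-depth prior: split probability
#'   `base * (1 + depth)^(-power)`.
#' @param nu,q Noise-variance prior degrees of freedom and calibration
#'   quantile (continuous outcomes).
#' @param numcut Maximum cutpoints per variable.
#' @param seed Integer seed.
#' @return An `inclusion_profile`: list with `proportions` (posterior-mean
#'   p-vector), `draws` (kept-draw by variable matrix), and `null_matrix`
#'   (`NULL` until [bart_permutation_null()] fills it).
#' @export
bart_fit <- function(data, y, family = c("binary", "continuous"),
                     n_trees = 20, n_burn = 1000, n_post = 1000,
                     k = 2, base = 0.95, power = 2, nu = 3, q = 0.9,
                     numcut = 100, seed = 1) {
  family <- match.arg(family)
  x <- as.matrix(data)
  set.seed(seed)
  fit <- bart_cpp(x, as.numeric(y), family == "binary",
                  as.integer(n_trees), as.integer(n_burn),
                  as.integer(n_post), base, power, k, nu, q,
                  as.integer(numcut))
  draws <- inclusion_draws(fit$varcount)
  structure(list(proportions = colMeans(draws), draws = draws,
                 p = ncol(x), variable_names = colnames(x),
                 null_matrix = NULL, P = 0L, family = family,
                 settings = list(n_trees = n_trees, n_burn = n_burn,
                                 n_post = n_post, k = k, base = base,
                                 power = power, numcut = numcut,
                                 seed = seed)),
            class = "inclusion_profile")
}

inclusion_draws <- function(varcount) {
  tot <- rowSums(varcount)
  draws <- varcount / ifelse(tot == 0, 1, tot)
  draws[tot == 0, ] <- 1 / ncol(varcount)
  draws
}

#' @export
print.inclusion_profile <- function(x, ...) {
  cat("<inclusion_profile> p =", x$p, ", kept draws =", nrow(x$draws), "\n")
  top <- order(x$proportions, decreasing = TRUE)[seq_len(min(5, x$p))]
  cat("  top proportions:",
      paste(sprintf("%s=%.3f", x$variable_names[top] %||% top,
                    x$proportions[top]), collapse = " "), "\n")
  if (!is.null(x$null_matrix)) {
    cat("  permutation null:", nrow(x$null_matrix), "refits\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permutation null distribution of BART inclusion proportions
#'
#' Refits BART `P` times on row-permuted outcomes; each refit contributes a
#' p-vector of posterior-mean inclusion proportions forming the null
#' distribution used by [bart_select()]. Permutation leaves the marginal
#' distribution of the outcome intact while destroying its association with
#' every covariate.
#'
#' @inheritParams bart_fit
#' @param profile An [bart_fit()] result for the observed outcome; the
#'   sampler settings are reused.
#' @param P Number of permutation refits (at least 1; values below 50 are
#'   statistically fragile).
#' @return The profile with `null_matrix` (`P` by `p`) filled in.
#' @export
bart_permutation_null <- function(data, y, profile, P = 100, seed = 1) {
  stopifnot(inherits(profile, "inclusion_profile"))
  if (P < 1) abort("P must be at least 1")
  x <- as.matrix(data)
  s <- profile$settings
  nm <- matrix(NA_real_, P, ncol(x))
  set.seed(seed)
  perm_seeds <- sample.int(.Machine$integer.max, P)
  for (i in seq_len(P)) {
    set.seed(perm_seeds[i])
    yp <- y[sample.int(length(y))]
    fit <- bart_fit(x, yp, profile$family, n_trees = s$n_trees,
                    n_burn = s$n_burn, n_post = s$n_post, k = s$k,
                    base = s$base, power = s$power, numcut = s$numcut,
                    seed = perm_seeds[i])
    nm[i, ] <- fit$proportions
  }
  profile$null_matrix <- nm
  profile$P <- as.integer(P)
  profile
}

#' Threshold BART inclusion proportions against their permutation null
#'
#' Three increasingly strict criteria: `local` selects a variable whose
#' observed inclusion proportion exceeds the `1 - alpha` empirical quantile
#' of its own null column; `global_se` uses thresholds `mean + C* * sd` of
#' each null column, with the smallest global multiplier `C*` such that at
#' least a `1 - alpha` fraction of permutation rows fall entirely below
#' their thresholds; `global_max` compares every variable against the
#' `1 - alpha` quantile of the per-permutation maximum proportion, giving
#' family-wise control (and typically selecting nothing under the null).
#' Null columns with zero spread fall back to their mean as the threshold.
#'
#' @param profile An `inclusion_profile` with `null_matrix` filled by
#'   [bart_permutation_null()].
#' @param criterion `"local"`, `"global_se"` or `"global_max"`.
#' @param alpha Quantile level.
#' @return A `selection_result` (method `BART-LOCAL`, `BART-GLOBALSE` or
#'   `BART-GLOBALMAX`); `stats` carries the per-variable thresholds.
#' @export
bart_select <- function(profile, criterion = c("local", "global_se",
                                               "global_max"),
                        alpha = 0.05) {
  criterion <- match.arg(criterion)
  if (is.null(profile$null_matrix)) {
    abort("profile has no permutation null; run bart_permutation_null() first")
  }
  nm <- profile$null_matrix
  prop <- profile$proportions
  thr <- switch(criterion,
    local = apply(nm, 2, quantile, probs = 1 - alpha),
    global_max = rep(quantile(apply(nm, 1, max), probs = 1 - alpha),
                     length(prop)),
    global_se = {
      mj <- colMeans(nm)
      sj <- apply(nm, 2, sd)
      std <- sweep(sweep(nm, 2, mj), 2, ifelse(sj == 0, Inf, sj), "/")
      ci <- apply(std, 1, max)  # per-permutation global multiplier needed
      cstar <- quantile(ci, probs = 1 - alpha, type = 1)
      mj + ifelse(sj == 0, 0, cstar * sj)
    })
  method <- switch(criterion, local = "BART-LOCAL",
                   global_se = "BART-GLOBALSE", global_max = "BART-GLOBALMAX")
  new_selection_result(method, which(prop > thr), p = length(prop),
                       variable_names = profile$variable_names,
                       tuning = list(criterion = criterion, alpha = alpha,
                                     P = profile$P),
                       stats = tibble(proportion = prop,
                                      threshold = unname(thr)))
}
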