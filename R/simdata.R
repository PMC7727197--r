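#' Describe a census-like synthetic covariate design
#'
#' A design records everything needed to draw a standardized covariate matrix
#' that emulates the structure of census-tract social-environmental tables:
#' skewed, zero-inflated marginal distributions and blocks of highly collinear
#' variables, with a low rate of missing values that are median-imputed.
#'
#' Covariates are drawn from a Gaussian copula: a latent multivariate normal
#' with the block-structured correlation target of [build_covariance()] is
#' transformed column-wise through monotone marginal maps, so rank (Spearman)
#' correlations of the latent field carry over to the observed scale.
#'
#' @param p Number of variables.
#' @param n Number of observations (at least 2).
#' @param blocks Collinearity blocks: a data frame (or tibble) with columns
#'   `size` and `rho`, one row per block. Block variables occupy the leading
#'   columns of the matrix in order. `rho` is the target absolute Spearman
#'   correlation within the block, in `[0, 1)`.
#' @param marginals Either a character vector of length `p` with entries
#'   `"gaussian"`, `"lognormal"` or `"zero_inflated"`, or a named numeric
#'   vector of proportions over those tags (cycled deterministically over
#'   columns).
#' @param zero_prob Probability of the zero mass point for zero-inflated
#'   columns, in `[0, 1)`.
#' @param missing_rate Probability that any entry is set missing before
#'   median imputation.
#' @param background Off-block latent correlation (default 0; must be
#'   at most 0.3).
#'
#' @return An object of class `covariate_design`.
#' @export
#' @examples
#' d <- covariate_design(p = 20, n = 100,
#'                       blocks = data.frame(size = 5, rho = 0.97))
#' X <- sample_covariates(d, seed = 1)
covariate_design <- function(p = 1000, n = 2000,
                             blocks = data.frame(size = c(rep(5, 8), rep(3, 10)),
                                                 rho = c(rep(0.97, 8), rep(0.5, 10))),
                             marginals = c(gaussian = 0.4, lognormal = 0.3,
                                           zero_inflated = 0.3),
                             zero_prob = 0.3,
                             missing_rate = 0.02,
                             background = 0) {
  stopifnot(p >= 1, n >= 2, missing_rate >= 0, missing_rate < 1,
            zero_prob >= 0, zero_prob < 1, background >= 0, background <= 0.3)
  blocks <- as_tibble(blocks)
  if (nrow(blocks) > 0) {
    stopifnot(all(c("size", "rho") %in% names(blocks)),
              all(blocks$size >= 2), all(blocks$rho >= 0), all(blocks$rho < 1))
    if (sum(blocks$size) > p) {
      abort("sum of block sizes exceeds p")
    }
  }
  tags <- c("gaussian", "lognormal", "zero_inflated")
  if (is.character(marginals)) {
    stopifnot(length(marginals) == p, all(marginals %in% tags))
    marginal <- marginals
  } else {
    stopifnot(is.numeric(marginals), all(names(marginals) %in% tags))
    props <- marginals / sum(marginals)
    counts <- floor(props * p)
    rem <- p - sum(counts)
    if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
    # collinear blocks are homogeneous in marginal shape (near-duplicate
    # census measures share a distributional kind, and mixing shapes within
    # a block would shrink observed Pearson correlations well below the
    # latent target); each block greedily takes the tag with the largest
    # remaining quota, loose columns cycle through what is left
    marginal <- character(p)
    pos <- 1L
    if (nrow(blocks) > 0) {
      for (b in seq_len(nrow(blocks))) {
        sz <- blocks$size[b]
        tag <- names(counts)[which.max(counts)]
        marginal[pos:(pos + sz - 1L)] <- tag
        counts[tag] <- counts[tag] - sz
        pos <- pos + sz
      }
    }
    rest <- rep(names(counts), times = pmax(counts, 0))
    need <- p - pos + 1L
    if (length(rest) < need) {
      rest <- c(rest, rep(names(props)[which.max(props)],
                          need - length(rest)))
    }
    if (pos <= p) marginal[pos:p] <- rest[seq_len(need)]
  }
  structure(
    list(p = as.integer(p), n = as.integer(n), blocks = blocks,
         marginal = marginal, zero_prob = zero_prob,
         missing_rate = missing_rate, background = background),
    class = "covariate_design")
}

#' @export
print.covariate_design <- function(x, ...) {
  cat("<covariate_design> p =", x$p, ", n =", x$n, "\n")
  if (nrow(x$blocks)) {
    cat("  blocks:", nrow(x$blocks), "(sizes",
        paste(range(x$blocks$size), collapse = "-"), ", |rho|",
        paste(range(x$blocks$rho), collapse = "-"), ")\n")
  } else cat("  blocks: none\n")
  cat("  marginals:", paste(names(table(x$marginal)),
                            table(x$marginal), collapse = ", "), "\n")
  cat("  missing_rate:", x$missing_rate,
      " zero_prob:", x$zero_prob, "\n")
  invisible(x)
}

#' Block-structured correlation target for a design
#'
#' Builds the latent p x p correlation matrix realizing the design's
#' collinearity blocks: within each block all off-diagonal entries equal the
#' block's target correlation, off-block entries equal the (low) background
#' correlation, and the diagonal is 1. If the result is not positive
#' semidefinite an eigenvalue floor at zero is applied and the matrix is
#' rescaled back to unit diagonal.
#'
#' @param design A [covariate_design()].
#' @return A p x p positive-semidefinite correlation matrix.
#' @export
build_covariance <- function(design) {
  stopifnot(inherits(design, "covariate_design"))
  p <- design$p
  sigma <- matrix(design$background, p, p)
  pos <- 1L
  if (nrow(design$blocks)) {
    for (b in seq_len(nrow(design$blocks))) {
      sz <- design$blocks$size[b]
      idx <- pos:(pos + sz - 1L)
      sigma[idx, idx] <- design$blocks$rho[b]
      pos <- pos + sz
    }
  }
  diag(sigma) <- 1
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    vals <- pmax(ev$values, 0)
    sigma <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(sigma))
    if (any(d <= 0)) abort("correlation target not repairable to PSD")
    sigma <- sigma / tcrossprod(d)
    diag(sigma) <- 1
  }
  sigma
}

marginal_transform <- function(z, tag, zero_prob) {
  u <- pnorm(z)
  switch(tag,
         gaussian = z,
         lognormal = exp(z),
         zero_inflated = {
           out <- numeric(length(u))
           pos <- u >= zero_prob
           out[pos] <- stats::qlnorm((u[pos] - zero_prob) / (1 - zero_prob))
           out
         },
         abort(paste0("unknown marginal tag: ", tag)))
}

#' Draw a standardized covariate matrix from a design
#'
#' Samples latent correlated Gaussians (via the Cholesky factor of
#' [build_covariance()]), pushes each column through its monotone marginal
#' transform (zero-inflated columns place mass `zero_prob` at zero), injects
#' missingness completely at random at the design's `missing_rate`, then
#' median-imputes and standardizes every column to mean 0, sd 1.
#'
#' @param design A [covariate_design()].
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param sigma Optional p x p correlation matrix overriding
#'   [build_covariance()] (used e.g. to construct confounding structures).
#' @param raw If `TRUE`, return the matrix after the marginal transform and
#'   missingness injection but before imputation and standardization.
#' @param max_attempts Redraw attempts when a column degenerates to constant.
#' @return A tibble with `n` rows and `p` columns `V0001`, ... Standardized
#'   unless `raw = TRUE`.
#' @export
sample_covariates <- function(design, seed, sigma = NULL, raw = FALSE,
                              max_attempts = 5L) {
  stopifnot(inherits(design, "covariate_design"))
  if (is.null(sigma)) sigma <- build_covariance(design)
  ch <- chol(sigma + diag(1e-10, design$p))
  set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    z <- matrix(rnorm(design$n * design$p), design$n) %*% ch
    x <- z
    for (j in seq_len(design$p)) {
      x[, j] <- marginal_transform(z[, j], design$marginal[j], design$zero_prob)
    }
    if (design$missing_rate > 0) {
      miss <- runif(length(x)) < design$missing_rate
      x[miss] <- NA_real_
    }
    ok <- apply(x, 2, function(col) {
      obs <- col[!is.na(col)]
      length(obs) >= 2 && var(obs) > 0
    })
    if (all(ok)) break
    if (attempt == max_attempts) {
      abort(paste0("degenerate (constant) columns after ", max_attempts,
                   " draws: ", paste(which(!ok), collapse = ", ")))
    }
  }
  colnames(x) <- sprintf("V%04d", seq_len(design$p))
  out <- as_tibble(x)
  if (raw) return(out)
  impute_and_standardize(out)
}

#' Median-impute missing entries and standardize columns
#'
#' Missing entries are replaced by the median of the observed entries in
#' their column; each column is then centered and scaled to mean 0 and
#' standard deviation 1 (n - 1 denominator). Standardization is idempotent.
#'
#' @param data A data frame or matrix of numeric covariates, possibly with
#'   missing entries.
#' @return A tibble of the same shape with no missing entries, each column
#'   mean 0 and sd 1.
#' @export
impute_and_standardize <- function(data) {
  x <- as.matrix(data)
  storage.mode(x) <- "double"
  nm <- colnames(x)
  if (is.null(nm)) nm <- sprintf("V%04d", seq_len(ncol(x)))
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    obs <- col[!is.na(col)]
    if (length(obs) < 2) {
      abort(paste0("column ", nm[j], " has fewer than 2 observed values"))
    }
    if (var(obs) == 0) {
      abort(paste0("column ", nm[j], " is constant"))
    }
    col[is.na(col)] <- median(obs)
    x[, j] <- (col - mean(col)) / sd(col)
  }
  colnames(x) <- nm
  as_tibble(x)
}

#' Pick true predictors from high- and low-collinearity pools
#'
#' Mirrors the benchmark's truth construction: 5 true variables are drawn
#' uniformly from the pool of variables with maximum absolute pairwise
#' correlation above `high` (markedly collinear with at least one other
#' variable) and 5 from the pool with all absolute correlations below `low`.
#'
#' @param data Standardized covariate tibble/matrix.
#' @param seed Integer seed.
#' @param n_high,n_low Number of picks from each pool.
#' @param high,low Correlation thresholds defining the pools (strict
#'   inequalities, absolute Pearson correlation).
#' @return A `truth_spec`: list with `indices` (high picks first), and the
#'   two pools used.
#' @export
choose_true_variables <- function(data, seed, n_high = 5L, n_low = 5L,
                                  high = 0.95, low = 0.6) {
  x <- as.matrix(data)
  cm <- abs(cor(x))
  diag(cm) <- 0
  maxcor <- apply(cm, 2, max)
  pool_high <- which(maxcor > high)
  pool_low <- which(maxcor < low)
  if (length(pool_high) < n_high || length(pool_low) < n_low) {
    abort(sprintf(
      "eligibility pools too small: %d high-collinearity (need %d), %d low-collinearity (need %d)",
      length(pool_high), n_high, length(pool_low), n_low))
  }
  set.seed(seed)
  hi <- sort(sample(pool_high, n_high))
  lo <- sort(sample(pool_low, n_low))
  structure(list(indices = c(hi, lo), high_indices = hi, low_indices = lo,
                 pool_high = pool_high, pool_low = pool_low,
                 high = high, low = low),
            class = "truth_spec")
}

#' @export
print.truth_spec <- function(x, ...) {
  cat("<truth_spec>", length(x$indices), "true variables\n")
  cat("  high-collinearity:", paste(x$high_indices, collapse = " "), "\n")
  cat("  low-collinearity: ", paste(x$low_indices, collapse = " "), "\n")
  invisible(x)
}

#' Power of a univariable two-sided Wald test
#'
#' Normal-approximation power for the slope of a standardized predictor. The
#' continuous case uses sampling standard error `1/sqrt(n)` (unit error
#' variance); the binary case uses `1/sqrt(n * pi * (1 - pi))` at baseline
#' prevalence `pi`.
#'
#' @param beta Standardized effect size.
#' @param n Sample size.
#' @param family `"binary"` or `"continuous"`.
#' @param alpha Two-sided type-I error.
#' @param prevalence Baseline outcome prevalence for the binary case.
#' @return Power in `[0, 1]`.
#' @export
wald_power <- function(beta, n, family = c("binary", "continuous"),
                       alpha = 5e-5, prevalence = 0.5) {
  family <- match.arg(family)
  se <- wald_se(n, family, prevalence)
  z <- qnorm(1 - alpha / 2)
  pnorm(abs(beta) / se - z) + pnorm(-abs(beta) / se - z)
}

wald_se <- function(n, family, prevalence = 0.5) {
  if (family == "binary") 1 / sqrt(n * prevalence * (1 - prevalence))
  else 1 / sqrt(n)
}

#' Calibrate the simulation effect size to a target power
#'
#' Returns the smallest effect size, rounded up to two decimals, whose
#' univariable two-sided Wald test on a standardized predictor attains at
#' least the requested power. At the benchmark's dimensions (n = 2000, 80%
#' power, two-sided alpha 5e-5) this gives 0.22 for binary outcomes and 0.11
#' for continuous outcomes.
#'
#' @inheritParams wald_power
#' @param power Target power in (0, 1).
#' @param digits Decimals to round the effect size up to.
#' @return The calibrated effect size (log-odds per SD for binary; outcome SD
#'   per predictor SD for continuous).
#' @export
#' @examples
#' calibrate_effect_size("binary", n = 2000)      # 0.22
#' calibrate_effect_size("continuous", n = 2000)  # 0.11
calibrate_effect_size <- function(family = c("binary", "continuous"),
                                  n = 2000, power = 0.8, alpha = 5e-5,
                                  prevalence = 0.5, digits = 2L) {
  family <- match.arg(family)
  stopifnot(power > 0, power < 1, alpha > 0, alpha < 1, n >= 2)
  se <- wald_se(n, family, prevalence)
  beta <- (qnorm(1 - alpha / 2) + qnorm(power)) * se
  if (!is.finite(beta)) abort("effect-size calibration infeasible")
  ceiling(beta * 10^digits - 1e-9) / 10^digits
}

#' Simulate outcomes from a sparse linear signal
#'
#' Continuous outcomes follow `y = X beta + e` with standard normal errors;
#' binary outcomes are Bernoulli with `logit(E(y)) = X beta`. `beta` is the
#' common effect size placed at the true indices and zero elsewhere; the
#' generating model has no intercept, so the binary baseline prevalence is
#' 0.5.
#'
#' @param data Standardized covariate tibble/matrix.
#' @param truth A `truth_spec` (or integer vector of true column indices).
#' @param beta Common effect size for the true variables.
#' @param family `"binary"` or `"continuous"`.
#' @param seed Integer seed.
#' @return A numeric vector of length `nrow(data)`; 0/1 valued for binary.
#' @export
simulate_outcome <- function(data, truth, beta,
                             family = c("binary", "continuous"), seed) {
  family <- match.arg(family)
  x <- as.matrix(data)
  idx <- if (inherits(truth, "truth_spec")) truth$indices else as.integer(truth)
  stopifnot(all(idx >= 1), all(idx <= ncol(x)), !anyDuplicated(idx))
  eta <- drop(x[, idx, drop = FALSE] %*% rep(beta, length(idx)))
  set.seed(seed)
  if (family == "binary") {
    rbinom(nrow(x), 1L, stats::plogis(eta))
  } else {
    eta + rnorm(nrow(x))
  }
}

#' Random discovery/validation split
#'
#' Partitions `1:n` uniformly at random into a discovery set of size
#' `round(2n/3)` and a validation set with the remainder.
#'
#' @param n Number of observations (at least 3).
#' @param seed Integer seed.
#' @return List with integer vectors `discovery` and `validation`.
#' @export
split_discovery_validation <- function(n, seed) {
  stopifnot(n >= 3)
  set.seed(seed)
  n_disc <- round(2 * n / 3)
  disc <- sort(sample.int(n, n_disc))
  list(discovery = disc, validation = setdiff(seq_len(n), disc))
}
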