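#' Validate selected variables on held-out data
#'
#' Univariable mode refits one model per selected variable on the validation
#' data and keeps those with two-sided Wald p-value below `p_threshold`
#' (0.05 by default). Lasso mode instead keeps the variables with nonzero
#' coefficients in a cross-validated lasso restricted to the selected
#' columns (a multivariable alternative intended to reduce confounding).
#'
#' @param selection A `selection_result`, or an integer vector of selected
#'   column indices.
#' @param data_val,y_val Validation covariates and outcome.
#' @param family `"binary"` or `"continuous"`.
#' @param mode `"univariable"` or `"lasso"`.
#' @param p_threshold Validation p-value threshold (univariable mode).
#' @param seed Seed for the lasso-mode CV folds.
#' @return The `selection_result` with its `validated` field filled, or an
#'   integer vector when `selection` was one. An empty selection validates
#'   to an empty set.
#' @export
validate_selection <- function(selection, data_val, y_val,
                               family = c("binary", "continuous"),
                               mode = c("univariable", "lasso"),
                               p_threshold = 0.05, seed = 1) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  is_result <- inherits(selection, "selection_result")
  selected <- if (is_result) selection$selected else
    sort(unique(as.integer(selection)))
  x <- as.matrix(data_val)
  stopifnot(all(selected >= 1), all(selected <= ncol(x)))
  if (length(selected) == 0) {
    validated <- integer(0)
  } else if (mode == "univariable" || length(selected) < 2) {
    st <- univ_tests(x[, selected, drop = FALSE], y_val, family)
    validated <- selected[st$p_value < p_threshold]
  } else {
    set.seed(seed)
    cv <- glmnet::cv.glmnet(x[, selected, drop = FALSE], y_val,
                            family = map_family(family), alpha = 1,
                            standardize = FALSE)
    validated <- selected[abs(coef(cv, s = "lambda.min")[-1]) > 1e-10]
  }
  if (!is_result) return(validated)
  selection$validated <- validated
  selection$tuning$validation_mode <- mode
  selection
}

#' Map true variables to their surrogates
#'
#' For each true variable `t`, the surrogate set is every non-true variable
#' whose absolute correlation with `t` exceeds `threshold` (strictly;
#' Pearson on the standardized matrix by default, Spearman by flag). Also
#' returns the surrogate pool (union over truths) and the relaxed
#' false-positive pool: non-true variables that are no one's surrogate.
#'
#' @param data Standardized covariate tibble/matrix.
#' @param truth A `truth_spec` or integer vector of true indices.
#' @param threshold Surrogate correlation threshold in (0, 1).
#' @param method `"pearson"` or `"spearman"`.
#' @return A `surrogate_map` list: `surrogates` (named list per truth),
#'   `pool` (union), `relaxed_null` (complement), `truth`.
#' @export
surrogate_map <- function(data, truth, threshold = 0.8,
                          method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(threshold > 0, threshold < 1)
  x <- as.matrix(data)
  idx <- if (inherits(truth, "truth_spec")) truth$indices else
    sort(as.integer(truth))
  cm <- abs(cor(x[, idx, drop = FALSE], x, method = method))
  surr <- lapply(seq_along(idx), function(i) {
    setdiff(which(cm[i, ] > threshold), idx)
  })
  names(surr) <- as.character(idx)
  pool <- sort(unique(unlist(surr)))
  structure(list(surrogates = surr, pool = pool,
                 relaxed_null = setdiff(seq_len(ncol(x)), c(idx, pool)),
                 truth = idx, threshold = threshold, method = method),
            class = "surrogate_map")
}

#' Strict true/false-positive accounting
#'
#' Counts a true positive only for exact members of the truth set; every
#' other validated variable is a false positive.
#'
#' @param validated Integer vector of validated indices (or a
#'   `selection_result` with `validated` filled).
#' @param truth A `truth_spec` or integer vector of true indices.
#' @return A one-row tibble with `tp`, `fp`, `fn`.
#' @export
score_strict <- function(validated, truth) {
  if (inherits(validated, "selection_result")) validated <- validated$validated
  idx <- if (inherits(truth, "truth_spec")) truth$indices else
    as.integer(truth)
  tp <- length(intersect(validated, idx))
  tibble(tp = tp, fp = length(setdiff(validated, idx)),
         fn = length(idx) - tp)
}

#' Surrogate-aware (relaxed) true/false-positive accounting
#'
#' A true variable counts as identified if it or any of its surrogates was
#' validated; each truth is counted at most once, so the maximum number of
#' true positives stays at the truth-set size. Surrogates leave the
#' false-positive pool: false positives are validated variables that are
#' neither truths nor surrogates.
#'
#' @inheritParams score_strict
#' @param surrogates A [surrogate_map()] computed on the same covariates.
#' @return A one-row tibble with `tp`, `fp`, `fn`.
#' @export
score_relaxed <- function(validated, truth, surrogates) {
  if (inherits(validated, "selection_result")) validated <- validated$validated
  stopifnot(inherits(surrogates, "surrogate_map"))
  idx <- if (inherits(truth, "truth_spec")) truth$indices else
    as.integer(truth)
  hit <- vapply(seq_along(idx), function(i) {
    idx[i] %in% validated ||
      length(intersect(surrogates$surrogates[[as.character(idx[i])]],
                       validated)) > 0
  }, TRUE)
  tp <- sum(hit)
  fp <- length(setdiff(validated, c(idx, surrogates$pool)))
  tibble(tp = tp, fp = fp, fn = length(idx) - tp)
}

#' F2 score
#'
#' Weighted F score `5 * TP / (5 * TP + 4 * FN + FP)`, which up-weights
#' sensitivity over precision; defined as 0 when all counts are zero.
#'
#' @param tp,fn,fp Non-negative counts (vectorized).
#' @return F2 in `[0, 1]`.
#' @export
f2_score <- function(tp, fn, fp) {
  stopifnot(all(tp >= 0), all(fn >= 0), all(fp >= 0))
  denom <- 5 * tp + 4 * fn + fp
  ifelse(denom == 0, 0, 5 * tp / denom)
}
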