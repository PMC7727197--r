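#' Configure a selection benchmark
#'
#' Bundles everything [run_benchmark()] needs: the covariate design, outcome
#' family, effect size (power-calibrated from the design's n when omitted),
#' the methods to compare, and the replication/seed plan. Method settings
#' omitted here fall back to the package defaults.
#'
#' @param design A [covariate_design()].
#' @param family `"binary"` or `"continuous"`.
#' @param methods Character vector from the method vocabulary
#'   (`UNIV-BFN`, `LASSO-MIN`, `LASSO-1SE`, `ELNET-MIN`, `ELNET-1SE`,
#'   `HCLST-CORR-SGL`, `HCLST-BOOT-SGL`, `RF`, `BAGGING`, `BART-LOCAL`,
#'   `BART-GLOBALSE`, `BART-GLOBALMAX`).
#' @param n_reps Number of outcome replicates.
#' @param master_seed Master seed; all per-replicate streams derive from it.
#' @param beta Common true effect size; default
#'   `calibrate_effect_size(family, n = design$n)`.
#' @param power,alpha Calibration targets used when `beta` is omitted.
#' @param validation_mode `"univariable"` or `"lasso"`.
#' @param surrogate_threshold Correlation threshold for the relaxed scoring.
#' @param settings Named list of per-method tuning overrides (`folds`,
#'   `mix`, `cut_height`, `nlambda`, `lambda_min_ratio`, `boot_B`,
#'   `boot_threshold`, `rf_trees`, `rf_subsamples`, `bart_trees`,
#'   `bart_burn`, `bart_post`, `bart_P`, `bart_alpha`).
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(design = covariate_design(),
                             family = c("binary", "continuous"),
                             methods = c("UNIV-BFN", "LASSO-MIN", "LASSO-1SE",
                                         "ELNET-MIN", "ELNET-1SE",
                                         "HCLST-CORR-SGL"),
                             n_reps = 500, master_seed = 20201210,
                             beta = NULL, power = 0.8, alpha = 5e-5,
                             validation_mode = c("univariable", "lasso"),
                             surrogate_threshold = 0.8,
                             settings = list()) {
  family <- match.arg(family)
  validation_mode <- match.arg(validation_mode)
  stopifnot(inherits(design, "covariate_design"),
            all(methods %in% method_vocabulary), n_reps >= 1)
  if (is.null(beta)) {
    beta <- calibrate_effect_size(family, n = design$n, power = power,
                                  alpha = alpha)
  }
  defaults <- list(folds = 10, mix = 0.95, cut_height = 0.2,
                   nlambda = 100, lambda_min_ratio = 0.001,
                   boot_B = 1000, boot_threshold = 0.95,
                   rf_trees = 1000, rf_subsamples = 100,
                   bart_trees = 20, bart_burn = 1000, bart_post = 1000,
                   bart_P = 100, bart_alpha = 0.05)
  structure(list(design = design, family = family, methods = methods,
                 n_reps = as.integer(n_reps),
                 master_seed = as.integer(master_seed), beta = beta,
                 validation_mode = validation_mode,
                 surrogate_threshold = surrogate_threshold,
                 settings = modifyList(defaults, settings)),
            class = "benchmark_config")
}

#' @export
print.benchmark_config <- function(x, ...) {
  cat("<benchmark_config>", x$family, "outcome, beta =", x$beta, "\n")
  cat("  design: p =", x$design$p, ", n =", x$design$n, "\n")
  cat("  methods:", paste(x$methods, collapse = ", "), "\n")
  cat("  replicates:", x$n_reps, " master seed:", x$master_seed, "\n")
  invisible(x)
}

# run the configured methods on the discovery data, reusing shared fits
# (one BART profile serves all three criteria); errors are captured per
# method as condition objects
run_methods_discovery <- function(methods, xd, yd, family, st, seed) {
  out <- list()
  safe <- function(expr) tryCatch(expr, error = function(e) e)
  if ("UNIV-BFN" %in% methods) {
    out[["UNIV-BFN"]] <- safe(univ_screen(xd, yd, family))
  }
  for (rule in c("min", "1se")) {
    id <- paste0("LASSO-", toupper(rule))
    if (id %in% methods) {
      out[[id]] <- safe(fit_penalized_cv(xd, yd, family, alpha_grid = 1,
                                         rule = rule, folds = st$folds,
                                         seed = seed, nlambda = st$nlambda,
                                         lambda_min_ratio = st$lambda_min_ratio))
    }
    id <- paste0("ELNET-", toupper(rule))
    if (id %in% methods) {
      out[[id]] <- safe(fit_penalized_cv(xd, yd, family,
                                         alpha_grid = elnet_alpha_grid(),
                                         rule = rule, folds = st$folds,
                                         seed = seed, nlambda = st$nlambda,
                                         lambda_min_ratio = st$lambda_min_ratio))
    }
  }
  if ("HCLST-CORR-SGL" %in% methods) {
    out[["HCLST-CORR-SGL"]] <- safe(
      hclst_sgl(xd, yd, family, "corr_threshold", cut_height = st$cut_height,
                mix = st$mix, folds = st$folds, seed = seed))
  }
  if ("HCLST-BOOT-SGL" %in% methods) {
    out[["HCLST-BOOT-SGL"]] <- safe(
      hclst_sgl(xd, yd, family, "bootstrap", B = st$boot_B,
                stability_threshold = st$boot_threshold,
                mix = st$mix, folds = st$folds, seed = seed))
  }
  for (mode in c("forest", "bagging")) {
    id <- if (mode == "forest") "RF" else "BAGGING"
    if (id %in% methods) {
      out[[id]] <- safe({
        v <- rf_vimp(xd, yd, family, mode = mode, n_trees = st$rf_trees,
                     n_subsamples = st$rf_subsamples, seed = seed)
        vimp_ci_select(v, alpha = st$bart_alpha)
      })
    }
  }
  bart_ids <- intersect(methods, c("BART-LOCAL", "BART-GLOBALSE",
                                   "BART-GLOBALMAX"))
  if (length(bart_ids)) {
    prof <- safe({
      pr <- bart_fit(xd, yd, family, n_trees = st$bart_trees,
                     n_burn = st$bart_burn, n_post = st$bart_post,
                     seed = seed)
      bart_permutation_null(xd, yd, pr, P = st$bart_P, seed = seed)
    })
    crits <- c("BART-LOCAL" = "local", "BART-GLOBALSE" = "global_se",
               "BART-GLOBALMAX" = "global_max")
    for (id in bart_ids) {
      out[[id]] <- if (inherits(prof, "error")) prof else
        safe(bart_select(prof, crits[[id]], alpha = st$bart_alpha))
    }
  }
  out[intersect(methods, names(out))]
}

#' Run the replicated selection benchmark
#'
#' Draws one covariate matrix from the design, picks the truth set (5
#' high-collinearity plus 5 low-collinearity variables by default), then for
#' each replicate simulates outcomes, splits 2/3 discovery / 1/3 validation,
#' runs every configured method on the discovery set, validates the
#' selections, and scores them under the strict and the surrogate-aware
#' relaxed definitions with F2 summaries. Method failures are recorded and
#' excluded from that method's means. Fully reproducible from the master
#' seed.
#'
#' @param config A [benchmark_config()].
#' @param verbose Print per-replicate progress.
#' @return A `benchmark_result`: list with `scores` (per replicate and
#'   method), `summary` (per-method means), `detection` (per true variable:
#'   detection rate per method and mean univariable effect estimate),
#'   `truth`, `surrogates`, `failures` and the config.
#' @export
run_benchmark <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "benchmark_config"))
  design <- config$design
  set.seed(config$master_seed)
  x_seed <- sample.int(2^31 - 2, 1)
  truth_seed <- sample.int(2^31 - 2, 1)
  rep_seeds <- matrix(sample.int(2^31 - 2, 3 * config$n_reps), ncol = 3)

  X <- sample_covariates(design, seed = x_seed)
  truth <- choose_true_variables(X, seed = truth_seed)
  smap <- surrogate_map(X, truth, threshold = config$surrogate_threshold)
  xm <- as.matrix(X)

  scores <- list()
  failures <- list()
  det_hits <- matrix(0, length(truth$indices), length(config$methods),
                     dimnames = list(as.character(truth$indices),
                                     config$methods))
  det_n <- setNames(numeric(length(config$methods)), config$methods)
  univ_est <- matrix(NA_real_, config$n_reps, length(truth$indices))

  for (r in seq_len(config$n_reps)) {
    y <- simulate_outcome(xm, truth, config$beta, config$family,
                          seed = rep_seeds[r, 1])
    sp <- split_discovery_validation(design$n, seed = rep_seeds[r, 2])
    xd <- xm[sp$discovery, , drop = FALSE]
    yd <- y[sp$discovery]
    xv <- xm[sp$validation, , drop = FALSE]
    yv <- y[sp$validation]
    univ_est[r, ] <- univ_tests(xd[, truth$indices, drop = FALSE], yd,
                                config$family)$estimate

    all_res <- run_methods_discovery(config$methods, xd, yd, config$family,
                                     config$settings, seed = rep_seeds[r, 3])
    sels <- list()
    for (id in names(all_res)) {
      if (inherits(all_res[[id]], "error")) {
        failures[[length(failures) + 1]] <-
          tibble(method_id = id, replicate = r,
                 message = conditionMessage(all_res[[id]]))
      } else {
        sels[[id]] <- all_res[[id]]
      }
    }

    for (id in names(sels)) {
      res <- validate_selection(sels[[id]], xv, yv, config$family,
                                mode = config$validation_mode,
                                seed = rep_seeds[r, 3])
      ss <- score_strict(res, truth)
      sr <- score_relaxed(res, truth, smap)
      scores[[length(scores) + 1]] <- tibble(
        method_id = id, replicate = r,
        n_selected = length(res$selected),
        n_validated = length(res$validated),
        tp_strict = ss$tp, fp_strict = ss$fp, fn_strict = ss$fn,
        tp_relaxed = sr$tp, fp_relaxed = sr$fp, fn_relaxed = sr$fn,
        f2_strict = f2_score(ss$tp, ss$fn, ss$fp),
        f2_relaxed = f2_score(sr$tp, sr$fn, sr$fp))
      det_hits[, id] <- det_hits[, id] +
        (truth$indices %in% res$validated)
      det_n[id] <- det_n[id] + 1
    }
    if (verbose) {
      counts <- vapply(sels, function(s) length(s$selected), 0L)
      message(sprintf("replicate %d/%d: %s", r, config$n_reps,
                      paste(names(counts), counts, sep = "=",
                            collapse = " ")))
    }
  }

  scores <- bind_rows(scores)
  summary <- scores %>%
    group_by(.data$method_id) %>%
    summarise(n_reps = dplyr::n(),
              across(c("tp_strict", "fp_strict", "f2_strict",
                       "tp_relaxed", "fp_relaxed", "f2_relaxed"), mean),
              f2_strict_of_means =
                f2_score(mean(.data$tp_strict), mean(.data$fn_strict),
                         mean(.data$fp_strict)),
              f2_relaxed_of_means =
                f2_score(mean(.data$tp_relaxed), mean(.data$fn_relaxed),
                         mean(.data$fp_relaxed)),
              .groups = "drop") %>%
    arrange(match(.data$method_id, method_vocabulary))

  detection <- tibble(
    truth_index = rep(truth$indices, times = length(config$methods)),
    variable = rep(colnames(xm)[truth$indices],
                   times = length(config$methods)),
    method_id = rep(config$methods, each = length(truth$indices)),
    detection_rate = as.vector(det_hits[, config$methods]) /
      pmax(rep(det_n[config$methods], each = length(truth$indices)), 1),
    mean_univ_estimate = rep(colMeans(univ_est, na.rm = TRUE),
                             times = length(config$methods)))

  structure(list(scores = scores, summary = summary, detection = detection,
                 truth = truth, surrogates = smap,
                 failures = bind_rows(failures), config = config,
                 beta = config$beta),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>", x$config$family, "outcome, beta =", x$beta,
      ",", x$config$n_reps, "replicates\n")
  print(as.data.frame(x$summary), digits = 3)
  if (nrow(x$failures)) {
    cat("  failed method runs:", nrow(x$failures), "\n")
  }
  invisible(x)
}

#' @rdname run_benchmark
#' @param x A `benchmark_result`.
#' @param ... Unused.
#' @method tidy benchmark_result
#' @export
tidy.benchmark_result <- function(x, ...) x$scores

#' @rdname run_benchmark
#' @method glance benchmark_result
#' @export
glance.benchmark_result <- function(x, ...) x$summary

#' Write benchmark result tables to CSV
#'
#' Emits `scores.csv` (per replicate), `summary.csv` (per-method means,
#' strict and relaxed) and `detection.csv` (per-true-variable detection
#' rates and mean univariable effect estimates). Output is deterministic:
#' two runs of [run_benchmark()] with the same master seed produce
#' byte-identical files.
#'
#' @param result A `benchmark_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_benchmark_csv <- function(result, dir) {
  stopifnot(inherits(result, "benchmark_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("scores.csv", "summary.csv", "detection.csv"))
  write.csv(result$scores, paths[1], row.names = FALSE)
  write.csv(result$summary, paths[2], row.names = FALSE)
  write.csv(result$detection, paths[3], row.names = FALSE)
  invisible(paths)
}
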