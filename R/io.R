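#' Read and write covariate matrices and sidecar metadata
#'
#' Covariate matrices travel as plain CSV (header row of variable names, one
#' row per observation, '.' decimal); a truth specification is serialized as
#' a JSON sidecar with the true indices, effect size, family and seed.
#'
#' @param data Covariate tibble/matrix.
#' @param path Output/input file path.
#' @return `write_covariates_csv()` returns the path invisibly;
#'   `read_covariates_csv()` a tibble.
#' @export
write_covariates_csv <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_covariates_csv
#' @export
read_covariates_csv <- function(path) {
  as_tibble(read.csv(path, check.names = FALSE))
}

#' @rdname write_covariates_csv
#' @param truth A `truth_spec`.
#' @param beta,family,seed Optional generation metadata stored alongside.
#' @export
write_truth_json <- function(truth, path, beta = NULL, family = NULL,
                             seed = NULL) {
  jsonlite::write_json(
    list(indices = truth$indices, high_indices = truth$high_indices,
         low_indices = truth$low_indices, beta = beta, family = family,
         seed = seed),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_covariates_csv
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(indices = as.integer(obj$indices),
                 high_indices = as.integer(obj$high_indices),
                 low_indices = as.integer(obj$low_indices),
                 beta = obj$beta, family = obj$family, seed = obj$seed),
            class = "truth_spec")
}

#' Serialize selection results and cluster assignments
#'
#' A selection result becomes a per-variable CSV (method, variable,
#' selected/validated flags) plus a JSON file with the tuning metadata; a
#' cluster assignment becomes a two-column CSV with a JSON sidecar (cut
#' height, method, number of groups).
#'
#' @param x A `selection_result` or `cluster_assignment`.
#' @param path CSV path; the JSON sidecar replaces the extension with
#'   `.json`.
#' @return The CSV path, invisibly.
#' @export
write_selection_csv <- function(x, path) {
  stopifnot(inherits(x, "selection_result"))
  tb <- tidy(x)
  tb$method_id <- x$method_id
  write.csv(tb[, c("method_id", "index", "variable", "selected_discovery",
                   "validated")], path, row.names = FALSE)
  jsonlite::write_json(x$tuning, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_selection_csv
#' @export
write_clusters_csv <- function(x, path) {
  stopifnot(inherits(x, "cluster_assignment"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  jsonlite::write_json(
    list(method = attr(x, "method"), cut_height = attr(x, "cut_height"),
         n_groups = attr(x, "n_groups"), B = attr(x, "B")),
    sub("\\.csv$", ".json", path), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(path)
}
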