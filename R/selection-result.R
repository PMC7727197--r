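#' Selection results
#'
#' All selection methods return a `selection_result`: the set of variable
#' indices selected on the discovery data, the subset that survived
#' validation (once [validate_selection()] has been applied), the method tag
#' from the benchmark's closed vocabulary, and the tuning values used.
#'
#' @name selection_result
NULL

method_vocabulary <- c("UNIV-BFN", "LASSO-MIN", "LASSO-1SE", "ELNET-MIN",
                       "ELNET-1SE", "HCLST-CORR-SGL", "HCLST-BOOT-SGL",
                       "RF", "BAGGING", "BART-LOCAL", "BART-GLOBALSE",
                       "BART-GLOBALMAX")

new_selection_result <- function(method_id, selected, p, variable_names = NULL,
                                 tuning = list(), stats = NULL, path = NULL,
                                 validated = NULL) {
  stopifnot(method_id %in% method_vocabulary)
  if (is.null(variable_names)) variable_names <- sprintf("V%04d", seq_len(p))
  selected <- sort(unique(as.integer(selected)))
  if (!is.null(validated)) {
    validated <- sort(unique(as.integer(validated)))
    stopifnot(all(validated %in% selected))
  }
  structure(list(method_id = method_id, selected = selected,
                 validated = validated, p = as.integer(p),
                 variable_names = variable_names, tuning = tuning,
                 stats = stats, path = path),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>", x$method_id, "\n")
  cat("  selected (discovery):", length(x$selected), "of", x$p, "\n")
  if (!is.null(x$validated)) {
    cat("  validated:           ", length(x$validated), "\n")
  }
  if (length(x$tuning)) {
    vals <- vapply(x$tuning, function(v) paste(format(v, digits = 4),
                                               collapse = ","), "")
    cat("  tuning:", paste(names(vals), vals, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' @rdname selection_result
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return `tidy()` gives one row per variable with logical selection flags;
#'   `glance()` a one-row summary.
#' @method tidy selection_result
#' @export
tidy.selection_result <- function(x, ...) {
  tibble(index = seq_len(x$p),
         variable = x$variable_names,
         selected_discovery = seq_len(x$p) %in% x$selected,
         validated = if (is.null(x$validated)) NA
                     else seq_len(x$p) %in% x$validated)
}

#' @rdname selection_result
#' @method glance selection_result
#' @export
glance.selection_result <- function(x, ...) {
  tibble(method_id = x$method_id,
         n_selected = length(x$selected),
         n_validated = if (is.null(x$validated)) NA_integer_
                       else length(x$validated))
}
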