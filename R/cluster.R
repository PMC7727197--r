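#' Spearman-correlation distance between variables
#'
#' Distance between columns defined as one minus the absolute Spearman rank
#' correlation, so perfectly (anti)monotone pairs are at distance 0 and
#' uncorrelated pairs near 1. Ties get average ranks.
#'
#' @param data Covariate tibble/matrix (no constant columns).
#' @return A symmetric p x p matrix with zero diagonal, entries in `[0, 1]`.
#' @export
spearman_distance_matrix <- function(data) {
  x <- as.matrix(data)
  sds <- apply(x, 2, sd)
  if (any(sds == 0 | is.na(sds))) {
    bad <- colnames(x)[which(sds == 0 | is.na(sds))]
    abort(paste0("constant column(s): ", paste(bad, collapse = ", ")))
  }
  d <- 1 - abs(cor(x, method = "spearman"))
  d[d < 0] <- 0
  d[d > 1] <- 1
  diag(d) <- 0
  d
}

# tolerant variant for bootstrap resamples: constant columns are maximally
# distant rather than an error
spearman_distance_tolerant <- function(x) {
  sds <- apply(x, 2, sd)
  bad <- sds == 0 | is.na(sds)
  if (any(bad)) x[1, bad] <- x[1, bad] + 1e-9  # break the tie arbitrarily
  suppressWarnings(cm <- cor(x, method = "spearman"))
  cm[is.na(cm)] <- 0
  d <- 1 - abs(cm)
  d[d < 0] <- 0; d[d > 1] <- 1
  diag(d) <- 0
  d
}

new_cluster_assignment <- function(labels, names, cut_height, method) {
  # relabel contiguously in order of first appearance
  labels <- match(labels, unique(labels))
  tb <- tibble(variable = names, group = as.integer(labels))
  structure(tb, class = c("cluster_assignment", class(tb)),
            cut_height = cut_height, method = method,
            n_groups = length(unique(labels)),
            sizes = as.integer(table(labels)))
}

#' @export
print.cluster_assignment <- function(x, ...) {
  sizes <- attr(x, "sizes")
  cat("<cluster_assignment>", nrow(x), "variables in", attr(x, "n_groups"),
      "groups (method:", attr(x, "method"), ")\n")
  cat("  multi-variable groups:", sum(sizes > 1),
      " largest:", max(sizes), "\n")
  NextMethod()
}

#' Complete-linkage clusters at a dendrogram height cut
#'
#' Agglomerative complete-linkage clustering of the Spearman distance matrix.
#' Clusters are the maximal groups whose merges all happen strictly below
#' `cut_height`; with the default cut of 0.2 every within-cluster pair
#' therefore has absolute Spearman correlation above 0.8 (a pair at exactly
#' 0.8 stays in separate clusters). Complete linkage keeps the merge height
#' interpretable as the worst within-cluster distance, and singletons are
#' common.
#'
#' @param D Distance matrix from [spearman_distance_matrix()] (or a `dist`).
#' @param cut_height Height cut in `[0, 1]`.
#' @return A `cluster_assignment` tibble (`variable`, `group`) with
#'   attributes `cut_height`, `method`, `n_groups`, `sizes`.
#' @export
hierarchical_clusters <- function(D, cut_height = 0.2) {
  dd <- if (inherits(D, "dist")) D else as.dist(D)
  nms <- attr(dd, "Labels")
  p <- attr(dd, "Size")
  if (is.null(nms)) nms <- sprintf("V%04d", seq_len(p))
  hc <- hclust(dd, method = "complete")
  k <- p - sum(hc$height < cut_height)
  labels <- cutree(hc, k = k)
  out <- new_cluster_assignment(labels, nms, cut_height, "corr_threshold")
  check_linkage_bound(as.matrix(dd), out)
  out
}

# complete-linkage guarantee: within-cluster max pairwise distance < cut
check_linkage_bound <- function(D, assignment) {
  for (g in unique(assignment$group)) {
    idx <- which(assignment$group == g)
    if (length(idx) > 1 &&
        max(D[idx, idx]) >= attr(assignment, "cut_height")) {
      abort("internal error: within-cluster distance exceeds the height cut")
    }
  }
  invisible(TRUE)
}

hclust_node_sets <- function(hc) {
  p <- length(hc$order)
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    pick <- function(v) if (v < 0) -v else members[[v]]
    members[[i]] <- sort(c(pick(hc$merge[i, 1]), pick(hc$merge[i, 2])))
  }
  members
}

#' Bootstrap-stability clusters
#'
#' Resamples observations with replacement `B` times, re-clusters each
#' replicate with the same Spearman-distance complete linkage, and scores
#' every internal node of the original dendrogram by the proportion of
#' replicates in which exactly the same member set appears as a dendrogram
#' node. Accepted clusters are the maximal non-overlapping nodes with
#' stability at or above `stability_threshold`; all remaining variables
#' become singletons. This is a stability-proportion criterion, not the
#' multiscale approximately-unbiased p-value of pvclust-style methods.
#'
#' @param data Covariate tibble/matrix.
#' @param B Number of bootstrap resamples (values below 100 trigger a
#'   warning).
#' @param stability_threshold Minimum stability proportion for acceptance.
#' @param seed Integer seed.
#' @return A `cluster_assignment` tibble.
#' @export
bootstrap_clusters <- function(data, B = 1000, stability_threshold = 0.95,
                               seed = 1) {
  x <- as.matrix(data)
  n <- nrow(x); p <- ncol(x)
  nms <- colnames(x)
  if (is.null(nms)) nms <- sprintf("V%04d", seq_len(p))
  if (B < 100) warn(paste0("B = ", B, " bootstrap resamples is low; ",
                           "stability estimates will be unstable"))
  if (n < 50) warn("fewer than 50 observations: resampling is unstable")
  D0 <- spearman_distance_matrix(x)
  hc0 <- hclust(as.dist(D0), method = "complete")
  nodes <- hclust_node_sets(hc0)
  # the root (all variables) is a node of every dendrogram: never a candidate
  nodes <- nodes[lengths(nodes) < p]
  keys <- vapply(nodes, paste, "", collapse = ",")
  hits <- integer(length(nodes))
  set.seed(seed)
  for (b in seq_len(B)) {
    rows <- sample.int(n, n, replace = TRUE)
    db <- spearman_distance_tolerant(x[rows, , drop = FALSE])
    hb <- hclust(as.dist(db), method = "complete")
    kb <- unique(vapply(hclust_node_sets(hb), paste, "", collapse = ","))
    hits <- hits + (keys %in% kb)
  }
  stability <- hits / B
  labels <- seq_len(p) + 10L * p  # provisional unique singleton labels
  ord <- order(lengths(nodes), decreasing = TRUE)
  taken <- logical(p)
  next_id <- 1L
  for (i in ord) {
    idx <- nodes[[i]]
    if (stability[i] >= stability_threshold && !any(taken[idx])) {
      labels[idx] <- next_id
      taken[idx] <- TRUE
      next_id <- next_id + 1L
    }
  }
  out <- new_cluster_assignment(labels, nms, NA_real_, "bootstrap")
  attr(out, "B") <- B
  attr(out, "stability_threshold") <- stability_threshold
  attr(out, "stability") <- stability
  out
}
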