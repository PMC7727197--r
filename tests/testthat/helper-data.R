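# standardized gaussian covariate matrix with variable names
std_norm_matrix <- function(n, p, seed = 1) {
  set.seed(seed)
  x <- scale(matrix(rnorm(n * p), n))
  colnames(x) <- sprintf("V%04d", seq_len(p))
  x
}

# small design with one tight block plus independent variables
one_block_design <- function(p = 20, n = 800, size = 5, rho = 0.97,
                             marginals = rep("gaussian", p),
                             missing_rate = 0) {
  covariate_design(p = p, n = n,
                   blocks = data.frame(size = size, rho = rho),
                   marginals = marginals, missing_rate = missing_rate)
}

# compare two partitions of the same variables up to label permutation
same_partition <- function(a, b) {
  key <- function(g) {
    split(seq_along(g), g) |>
      lapply(function(s) paste(sort(s), collapse = ",")) |>
      unlist() |> sort() |> unname()
  }
  identical(key(a), key(b))
}

# objective of the sparse group lasso problem (gaussian or binomial)
sgl_objective <- function(x, y, family, beta, b0, lambda, mix, gvec) {
  eta <- b0 + drop(x %*% beta)
  loss <- if (family == "binary") {
    mean(log(1 + exp(eta)) - y * eta)
  } else {
    mean((y - eta)^2) / 2
  }
  gw <- sqrt(table(gvec))
  grp <- vapply(split(beta, gvec), function(b) sqrt(sum(b^2)), 0)
  loss + lambda * ((1 - mix) * sum(gw * grp) + mix * sum(abs(beta)))
}
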