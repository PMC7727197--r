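test_that("covariance targets realize the requested block structure", {
  d <- covariate_design(p = 10, n = 100,
                        blocks = data.frame(size = 5, rho = 0.97),
                        missing_rate = 0)
  s <- build_covariance(d)
  expect_equal(s[1:5, 1:5], matrix(0.97, 5, 5) + diag(0.03, 5))
  expect_equal(s[6:10, 6:10], diag(5))
  expect_equal(s[1:5, 6:10], matrix(0, 5, 5))

  d0 <- covariate_design(p = 6, n = 50,
                         blocks = data.frame(size = integer(), rho = numeric()))
  expect_equal(build_covariance(d0), diag(6))

  # extreme block survives the eigenvalue floor
  dx <- covariate_design(p = 60, n = 100,
                         blocks = data.frame(size = 50, rho = 0.999))
  sx <- build_covariance(dx)
  expect_gte(min(eigen(sx, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  expect_equal(unname(diag(sx)), rep(1, 60))
})

test_that("design invariants are enforced", {
  expect_error(covariate_design(p = 5, n = 100,
                                blocks = data.frame(size = 6, rho = 0.9)),
               "block sizes")
  expect_error(covariate_design(p = 10, n = 100,
                                blocks = data.frame(size = 3, rho = 1.0)))
  expect_error(covariate_design(p = 10, n = 1))
})

test_that("median imputation and standardization follow the stated recipe", {
  out <- impute_and_standardize(cbind(a = c(1, NA, 3)))
  expect_equal(out$a, c(-1, 0, 1))

  # hand arithmetic: c(0,0,0,0,10) has mean 2 and sd sqrt(20)
  out2 <- impute_and_standardize(cbind(b = c(0, 0, 0, 0, 10)))
  expect_equal(mean(out2$b), 0, tolerance = 1e-12)
  expect_equal(sd(out2$b), 1, tolerance = 1e-12)
  expect_equal(max(out2$b), (10 - 2) / sqrt(20))

  # idempotence on complete standardized input
  x <- std_norm_matrix(50, 4)
  once <- impute_and_standardize(x)
  twice <- impute_and_standardize(once)
  expect_equal(as.matrix(twice), as.matrix(once), tolerance = 1e-12)

  # standardization commutes with column permutation
  perm <- c(3, 1, 4, 2)
  expect_equal(as.matrix(impute_and_standardize(x[, perm])),
               as.matrix(impute_and_standardize(x))[, perm])

  expect_error(impute_and_standardize(cbind(ok = 1:5, flat = rep(2, 5))),
               "flat")
  expect_error(impute_and_standardize(cbind(gone = c(NA, NA, 1))), "gone")
})

test_that("sampled covariates hit the target rank correlations and margins", {
  d <- covariate_design(p = 30, n = 2000,
                        blocks = data.frame(size = 5, rho = 0.97))
  x <- as.matrix(sample_covariates(d, seed = 101))
  expect_false(anyNA(x))
  expect_equal(unname(colMeans(x)), rep(0, 30), tolerance = 1e-8)
  expect_equal(unname(apply(x, 2, sd)), rep(1, 30), tolerance = 1e-8)
  sc <- abs(cor(x[, 1:5], method = "spearman"))
  expect_true(all(sc[upper.tri(sc)] >= 0.92))

  # zero-inflation places the stated mass at the minimum
  dz <- covariate_design(p = 5, n = 2000,
                         blocks = data.frame(size = integer(),
                                             rho = numeric()),
                         marginals = rep("zero_inflated", 5),
                         zero_prob = 0.5, missing_rate = 0)
  raw <- as.matrix(sample_covariates(dz, seed = 7, raw = TRUE))
  expect_lt(abs(mean(raw == 0) - 0.5), 0.03)

  # no missingness: imputation changes nothing
  d0 <- covariate_design(p = 6, n = 300,
                         blocks = data.frame(size = integer(),
                                             rho = numeric()),
                         missing_rate = 0)
  raw0 <- sample_covariates(d0, seed = 3, raw = TRUE)
  expect_false(anyNA(raw0))
  expect_equal(as.matrix(sample_covariates(d0, seed = 3)),
               as.matrix(impute_and_standardize(raw0)))
})

test_that("copula transform preserves rank correlation for monotone marginals", {
  d <- covariate_design(p = 2, n = 5000,
                        blocks = data.frame(size = 2, rho = 0.8),
                        marginals = c("gaussian", "lognormal"),
                        missing_rate = 0)
  x <- as.matrix(sample_covariates(d, seed = 5))
  # latent Spearman for bivariate normal rho: (6/pi) asin(rho/2)
  target <- (6 / pi) * asin(0.8 / 2)
  expect_lt(abs(cor(x[, 1], x[, 2], method = "spearman") - target), 0.03)
})

test_that("true-variable pools match a brute-force correlation scan", {
  d <- one_block_design(p = 20, n = 1500)
  x <- as.matrix(sample_covariates(d, seed = 11))
  truth <- choose_true_variables(x, seed = 2)
  cm <- abs(cor(x))
  maxcor <- vapply(seq_len(20), function(j) max(cm[j, -j]), 0)
  expect_setequal(truth$pool_high, which(maxcor > 0.95))
  expect_setequal(truth$pool_low, which(maxcor < 0.6))
  # the only 0.97-block is forced to be the high-collinearity picks
  expect_setequal(truth$high_indices, 1:5)
  expect_length(truth$indices, 10)
  # deterministic given seed
  expect_identical(choose_true_variables(x, seed = 2)$indices, truth$indices)

  # independent matrix: the high-collinearity pool is empty
  expect_error(choose_true_variables(std_norm_matrix(1500, 10, seed = 1),
                                     seed = 1),
               "pools too small")
})

test_that("effect-size calibration matches closed-form normal quantiles", {
  expect_identical(calibrate_effect_size("binary", n = 2000), 0.22)
  expect_identical(calibrate_effect_size("continuous", n = 2000), 0.11)
  # derived example at conventional alpha
  expect_identical(
    calibrate_effect_size("continuous", n = 2000, alpha = 0.05),
    ceiling(100 * (qnorm(0.975) + qnorm(0.8)) / sqrt(2000)) / 100)
  # monotone decreasing in n and alpha
  expect_lte(calibrate_effect_size("binary", n = 4000),
             calibrate_effect_size("binary", n = 2000))
  expect_lte(calibrate_effect_size("binary", n = 2000, alpha = 1e-3),
             calibrate_effect_size("binary", n = 2000, alpha = 5e-5))
  expect_error(calibrate_effect_size("binary", n = 2000, power = 1.2))
})

test_that("simulated outcomes follow the sparse generating model", {
  x <- std_norm_matrix(2000, 5, seed = 9)
  yb <- simulate_outcome(x, 1:2, beta = 0, family = "binary", seed = 1)
  expect_true(all(yb %in% c(0, 1)))
  expect_lt(abs(mean(yb) - 0.5), 3 * 0.5 / sqrt(2000))

  yc <- simulate_outcome(x, 1:2, beta = 0, family = "continuous", seed = 1)
  expect_lt(abs(var(yc) - 1), 0.15)

  expect_identical(simulate_outcome(x, 1:2, 0.5, "binary", seed = 4),
                   simulate_outcome(x, 1:2, 0.5, "binary", seed = 4))

  # univariable OLS recovers beta for an independent true variable
  slopes <- vapply(1:200, function(s) {
    y <- simulate_outcome(x, 3, beta = 0.11, family = "continuous", seed = s)
    sum(x[, 3] * (y - mean(y))) / sum(x[, 3]^2)
  }, 0)
  expect_lt(abs(mean(slopes) - 0.11), 0.01)
})

test_that("discovery/validation split has the stated sizes and is random", {
  s <- split_discovery_validation(2000, seed = 1)
  expect_length(s$discovery, 1333)
  expect_length(s$validation, 667)
  expect_identical(sort(c(s$discovery, s$validation)), 1:2000)

  s3 <- split_discovery_validation(3, seed = 1)
  expect_length(s3$discovery, 2)
  expect_length(s3$validation, 1)

  expect_identical(split_discovery_validation(100, seed = 5),
                   split_discovery_validation(100, seed = 5))
  for (n in c(10, 47, 301)) {
    s <- split_discovery_validation(n, seed = n)
    expect_length(s$discovery, round(2 * n / 3))
    expect_length(intersect(s$discovery, s$validation), 0)
    expect_identical(sort(c(s$discovery, s$validation)), seq_len(n))
  }
})
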