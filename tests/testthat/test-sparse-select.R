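test_that("univariable screening uses the Bonferroni default and finds strong effects", {
  x <- std_norm_matrix(60, 1000, seed = 2)
  y <- rnorm(60)
  r <- univ_screen(x, y, "continuous")
  expect_equal(r$tuning$p_threshold, 5e-5)
  expect_s3_class(r, "selection_result")
  expect_equal(r$method_id, "UNIV-BFN")
  # global null at the Bonferroni threshold: essentially nothing selected
  expect_lte(length(r$selected), 3)

  x2 <- std_norm_matrix(500, 10, seed = 3)
  y2 <- simulate_outcome(x2, 4, beta = 2, family = "continuous", seed = 1)
  expect_true(4 %in% univ_screen(x2, y2, "continuous")$selected)
  yb <- simulate_outcome(x2, 4, beta = 2, family = "binary", seed = 1)
  expect_true(4 %in% univ_screen(x2, yb, "binary")$selected)
})

test_that("gaussian screening agrees with lm Wald tests", {
  x <- std_norm_matrix(80, 5, seed = 4)
  y <- simulate_outcome(x, 2, beta = 0.5, family = "continuous", seed = 2)
  st <- censelect:::univ_tests(x, y, "continuous")
  for (j in 1:5) {
    fit <- summary(lm(y ~ x[, j]))$coefficients
    expect_equal(st$estimate[j], fit[2, 1], tolerance = 1e-10)
    expect_equal(st$p_value[j], fit[2, 4], tolerance = 1e-10)
  }
})

test_that("binary screening agrees with glm Wald tests", {
  x <- std_norm_matrix(150, 4, seed = 5)
  y <- simulate_outcome(x, 1, beta = 0.8, family = "binary", seed = 3)
  st <- censelect:::univ_tests(x, y, "binary")
  for (j in 1:4) {
    fit <- summary(glm(y ~ x[, j], family = binomial()))$coefficients
    expect_equal(st$estimate[j], fit[2, 1], tolerance = 1e-6)
    expect_equal(st$p_value[j], fit[2, 4], tolerance = 1e-5)
  }
})

test_that("lasso splits duplicated pairs, elastic net keeps them together", {
  set.seed(6)
  n <- 300
  x1 <- rnorm(n)
  x <- scale(cbind(x1, x1, matrix(rnorm(n * 8), n)))
  colnames(x) <- sprintf("V%02d", 1:10)
  y <- drop(0.8 * x[, 1]) + rnorm(n)
  rl <- fit_penalized_cv(x, y, "continuous", alpha_grid = 1, rule = "min",
                         seed = 1)
  expect_lte(sum(c(1, 2) %in% rl$selected), 1)
  re <- fit_penalized_cv(x, y, "continuous", alpha_grid = 0.5, rule = "min",
                         seed = 1)
  expect_setequal(intersect(re$selected, 1:2), 1:2)
  b <- re$stats$estimate[1:2]
  expect_lt(abs(b[1] - b[2]) / mean(abs(b)), 0.05)
})

test_that("the 1SE rule is at least as conservative as the minimum rule", {
  x <- std_norm_matrix(200, 40, seed = 7)
  y <- simulate_outcome(x, 1:4, beta = 0.4, family = "continuous", seed = 4)
  rmin <- fit_penalized_cv(x, y, "continuous", alpha_grid = 1, rule = "min",
                           seed = 9)
  r1se <- fit_penalized_cv(x, y, "continuous", alpha_grid = 1, rule = "1se",
                           seed = 9)
  expect_gte(r1se$tuning$lambda, rmin$tuning$lambda)
  expect_lte(length(r1se$selected), length(rmin$selected))
  expect_equal(rmin$method_id, "LASSO-MIN")
  expect_equal(r1se$method_id, "LASSO-1SE")
  # CV path metadata is aligned with the grid
  expect_equal(nrow(rmin$path), length(rmin$path$lambda))
  expect_true(all(diff(rmin$path$lambda) < 0))
})

test_that("fitted lasso solutions satisfy the KKT conditions", {
  x <- std_norm_matrix(150, 30, seed = 8)
  y <- simulate_outcome(x, 1:3, beta = 0.5, family = "continuous", seed = 5)
  r <- fit_penalized_cv(x, y, "continuous", alpha_grid = 1, rule = "min",
                        seed = 2)
  ok <- check_kkt(x, y, "continuous", r$stats$estimate,
                  r$tuning$intercept, r$tuning$lambda, alpha = 1)
  expect_true(as.logical(ok))

  yb <- simulate_outcome(x, 1:3, beta = 0.5, family = "binary", seed = 5)
  rb <- fit_penalized_cv(x, yb, "binary", alpha_grid = 1, rule = "min",
                         seed = 2)
  okb <- check_kkt(x, yb, "binary", rb$stats$estimate,
                   rb$tuning$intercept, rb$tuning$lambda, alpha = 1)
  expect_true(as.logical(okb))
})

test_that("selection results keep their invariants and tidy output", {
  x <- std_norm_matrix(100, 8, seed = 10)
  y <- simulate_outcome(x, 1, beta = 1.5, family = "continuous", seed = 6)
  r <- univ_screen(x, y, "continuous")
  td <- tidy(r)
  expect_equal(nrow(td), 8)
  expect_equal(sum(td$selected_discovery), length(r$selected))
  expect_true(all(is.na(td$validated)))
  g <- glance(r)
  expect_equal(g$n_selected, length(r$selected))
  expect_error(censelect:::new_selection_result("NOT-A-METHOD", 1, 5))
  # validated must be a subset of the discovery selection
  expect_error(censelect:::new_selection_result("UNIV-BFN", 1, 5,
                                                validated = 2))
})
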