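test_that("with singleton groups the solver reproduces the lasso", {
  # mix = 1 is exactly the lasso; mix = 0 with unit group weights too
  for (i in 1:5) {
    set.seed(100 + i)
    n <- 60 + 10 * i; p <- 10 + 2 * i
    x <- scale(matrix(rnorm(n * p), n))
    colnames(x) <- sprintf("V%02d", seq_len(p))
    y <- drop(x %*% c(rep(0.7, 3), rep(0, p - 3))) + rnorm(n)
    lam <- 0.05 + 0.02 * i
    ref <- glmnet::glmnet(x, y, alpha = 1, lambda = lam,
                          standardize = FALSE, thresh = 1e-12)
    for (mix in c(1, 0)) {
      fit <- sgl_fit(x, y, "continuous", groups = seq_len(p), mix = mix,
                     lambda = lam, cv = FALSE, tol = 1e-9)
      expect_lt(max(abs(as.numeric(coef(ref))[-1] - fit$stats$estimate)),
                1e-5)
    }
    yb <- rbinom(n, 1, plogis(drop(x %*% c(rep(0.7, 3), rep(0, p - 3)))))
    refb <- glmnet::glmnet(x, yb, family = "binomial", alpha = 1,
                           lambda = lam, standardize = FALSE, thresh = 1e-12)
    fitb <- sgl_fit(x, yb, "binary", groups = seq_len(p), mix = 1,
                    lambda = lam, cv = FALSE, tol = 1e-9)
    expect_lt(max(abs(as.numeric(coef(refb))[-1] - fitb$stats$estimate)),
              1e-5)
  }
})

test_that("the penalty zeroes every group at and above lambda_max", {
  x <- std_norm_matrix(120, 15, seed = 31)
  y <- simulate_outcome(x, 1:2, beta = 0.8, family = "continuous", seed = 1)
  gr <- c(rep(1, 5), 2:11)
  gv <- censelect:::group_vector(gr, 15)
  ord <- order(gv)
  sizes <- as.numeric(table(gv))
  gend <- as.integer(cumsum(sizes) - 1L)
  gstart <- as.integer(c(0L, head(gend, -1) + 1L))
  lmax <- censelect:::sgl_lambda_max_cpp(x[, ord], y, FALSE, gstart, gend,
                                         sqrt(sizes), 0.95)
  for (lam in c(lmax, 1.5 * lmax)) {
    fit <- sgl_fit(x, y, "continuous", groups = gr, mix = 0.95, lambda = lam,
                   cv = FALSE)
    expect_length(fit$selected, 0)
  }
  # just below lambda_max something enters
  fit2 <- sgl_fit(x, y, "continuous", groups = gr, mix = 0.95,
                  lambda = 0.95 * lmax, cv = FALSE)
  expect_gt(length(fit2$selected), 0)
})

test_that("group structure drives selection: within-group sparsity holds", {
  set.seed(32)
  n <- 300; p <- 15
  x <- scale(matrix(rnorm(n * p), n))
  colnames(x) <- sprintf("V%02d", seq_len(p))
  y <- drop(x[, 1]) + rnorm(n)
  gr <- c(rep(1, 5), 6:15)
  fit <- sgl_fit(x, y, "continuous", groups = gr, mix = 0.5, lambda = 0.12,
                 cv = FALSE)
  b <- fit$stats$estimate
  expect_true(1 %in% fit$selected)            # the signal member is kept
  expect_lt(sum(b[1:5] != 0), 5)              # some within-group zeros
  expect_true(all(which(b != 0) %in% fit$selected))
})

test_that("solutions satisfy the sparse-group-lasso stationarity conditions", {
  set.seed(33)
  n <- 200; p <- 12
  x <- scale(matrix(rnorm(n * p), n))
  colnames(x) <- sprintf("V%02d", seq_len(p))
  y <- drop(x %*% c(0.8, 0.8, rep(0, p - 2))) + rnorm(n)
  gr <- c(rep(1, 4), rep(2, 4), 9:12)
  mix <- 0.7; lam <- 0.08
  fit <- sgl_fit(x, y, "continuous", groups = gr, mix = mix, lambda = lam,
                 cv = FALSE, tol = 1e-9)
  b <- fit$stats$estimate
  eta <- fit$tuning$intercept + drop(x %*% b)
  grad <- -drop(crossprod(x, y - eta)) / n
  gv <- censelect:::group_vector(gr, p)
  for (g in unique(gv)) {
    idx <- which(gv == g)
    wg <- sqrt(length(idx))
    if (all(b[idx] == 0)) {
      s <- pmax(abs(grad[idx]) - lam * mix, 0) * sign(grad[idx])
      expect_lte(sqrt(sum(s^2)), lam * (1 - mix) * wg + 1e-6)
    } else {
      gnorm <- sqrt(sum(b[idx]^2))
      for (j in idx) {
        if (b[j] != 0) {
          expected <- -lam * mix * sign(b[j]) -
            lam * (1 - mix) * wg * b[j] / gnorm
          expect_lt(abs(grad[j] - expected), 1e-6)
        } else {
          expect_lte(abs(grad[j]), lam * mix + 1e-6)
        }
      }
    }
  }
  # the returned solution is a local minimum of the objective
  obj0 <- sgl_objective(x, y, "continuous", b, fit$tuning$intercept,
                        lam, mix, gv)
  set.seed(1)
  for (k in 1:50) {
    pert <- b + rnorm(p, sd = 1e-3)
    expect_gte(sgl_objective(x, y, "continuous", pert, fit$tuning$intercept,
                             lam, mix, gv), obj0 - 1e-12)
  }
})

test_that("clustered SGL composes clustering with the solver", {
  set.seed(34)
  x <- std_norm_matrix(300, 12, seed = 34)
  y <- simulate_outcome(x, 7, beta = 1.2, family = "continuous", seed = 2)
  r <- hclst_sgl(x, y, "continuous", "corr_threshold", folds = 5, seed = 2)
  expect_equal(r$method_id, "HCLST-CORR-SGL")
  expect_true(7 %in% r$selected)
  expect_equal(r$tuning$n_groups, 12L)  # independent columns: all singletons

  # signal inside a tight block: the block forms one group that is selected
  d <- one_block_design(p = 20, n = 800)
  xb <- sample_covariates(d, seed = 4)
  yb <- simulate_outcome(xb, 1, beta = 0.5, family = "continuous", seed = 5)
  rb <- hclst_sgl(xb, yb, "continuous", "corr_threshold", folds = 5, seed = 2)
  expect_gt(length(intersect(rb$selected, 1:5)), 0)
  expect_lt(rb$tuning$n_groups, 20)

  rboot <- hclst_sgl(xb, yb, "continuous", "bootstrap", B = 100,
                     folds = 5, seed = 2)
  expect_equal(rboot$method_id, "HCLST-BOOT-SGL")
  expect_gt(length(intersect(rboot$selected, 1:5)), 0)
})
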