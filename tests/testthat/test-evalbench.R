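test_that("strict scoring counts exact truths only", {
  truth <- 1:10
  expect_equal(unlist(score_strict(1:10, truth)), c(tp = 10, fp = 0, fn = 0))
  expect_equal(unlist(score_strict(integer(0), truth)),
               c(tp = 0, fp = 0, fn = 10))
  expect_equal(unlist(score_strict(c(1:10, 11, 12, 13), truth)),
               c(tp = 10, fp = 3, fn = 0))
})

test_that("surrogate maps match a brute-force correlation scan", {
  d <- one_block_design(p = 20, n = 1000)
  x <- as.matrix(sample_covariates(d, seed = 61))
  truth <- c(1, 8, 15)
  sm <- surrogate_map(x, truth, threshold = 0.8)
  cm <- abs(cor(x))
  for (t in truth) {
    expect_setequal(sm$surrogates[[as.character(t)]],
                    setdiff(which(cm[t, ] > 0.8), truth))
  }
  expect_setequal(sm$pool, sort(unique(unlist(sm$surrogates))))
  expect_setequal(sm$relaxed_null,
                  setdiff(1:20, c(truth, sm$pool)))

  # independent covariates: no surrogates, full relaxed pool
  xi <- std_norm_matrix(500, 15, seed = 62)
  smi <- surrogate_map(xi, 1:10)
  expect_true(all(lengths(smi$surrogates) == 0))
  expect_length(smi$relaxed_null, 5)
})

test_that("relaxed scoring credits surrogates once and shrinks the FP pool", {
  set.seed(63)
  base <- matrix(rnorm(400 * 12), 400)
  base[, 11] <- base[, 1] + rnorm(400, sd = 0.1)  # surrogate of variable 1
  base[, 12] <- base[, 1] + rnorm(400, sd = 0.1)  # second surrogate
  x <- scale(base)
  colnames(x) <- sprintf("V%02d", 1:12)
  truth <- 1:10
  sm <- surrogate_map(x, truth)
  expect_setequal(sm$surrogates[["1"]], c(11, 12))

  # only a surrogate of truth 1 validated: one relaxed TP, no FP
  expect_equal(unlist(score_relaxed(11, truth, sm)),
               c(tp = 1, fp = 0, fn = 9))
  # the truth plus two of its surrogates still count once
  expect_equal(unlist(score_relaxed(c(1, 11, 12), truth, sm)),
               c(tp = 1, fp = 0, fn = 9))
  # strict scoring sees the surrogates as false positives
  expect_equal(unlist(score_strict(c(1, 11, 12), truth)),
               c(tp = 1, fp = 2, fn = 9))

  # a variable that is neither truth nor surrogate stays a false positive
  xi <- std_norm_matrix(500, 15, seed = 64)
  smi <- surrogate_map(xi, 1:10)
  expect_equal(unlist(score_relaxed(11, 1:10, smi)),
               c(tp = 0, fp = 1, fn = 10))

  # consistency invariants over random validated sets
  for (k in 1:20) {
    set.seed(k)
    v <- sample(12, sample(0:8, 1))
    ss <- score_strict(v, truth)
    sr <- score_relaxed(v, truth, sm)
    expect_gte(sr$tp, ss$tp)
    expect_lte(sr$fp, ss$fp)
    expect_equal(ss$tp + ss$fn, 10)
    expect_equal(sr$tp + sr$fn, 10)
  }
})

test_that("the F2 score follows its formula and monotonicities", {
  expect_equal(f2_score(10, 0, 0), 1)
  expect_equal(f2_score(0, 10, 7), 0)
  expect_equal(f2_score(5, 5, 5), 0.5)  # 25 / 50
  expect_equal(f2_score(0, 0, 0), 0)
  expect_equal(f2_score(4, 6, 32), 5 * 4 / (5 * 4 + 4 * 6 + 32))
  for (k in 1:25) {
    set.seed(k)
    tp <- sample(0:10, 1); fn <- 10 - tp; fp <- sample(0:40, 1)
    f <- f2_score(tp, fn, fp)
    expect_true(f >= 0 && f <= 1)
    if (tp > 0) {
      expect_equal(f == 1, fn == 0 && fp == 0)
      expect_gte(f2_score(tp, fn, fp), f2_score(max(tp - 1, 0), fn + 1, fp))
      expect_gte(f, f2_score(tp, fn, fp + 1))
    }
  }
})

test_that("validation keeps real effects and drops noise at the stated rates", {
  x <- std_norm_matrix(400, 6, seed = 65)
  y <- simulate_outcome(x, 2, beta = 0.5, family = "continuous", seed = 1)
  expect_identical(validate_selection(integer(0), x, y, "continuous"),
                   integer(0))
  v <- validate_selection(c(2, 5), x, y, "continuous")
  expect_true(2 %in% v)

  # a pure-noise variable validates about 5% of the time
  hits <- vapply(1:400, function(s) {
    yn <- simulate_outcome(x, 2, beta = 0, family = "continuous", seed = s)
    length(validate_selection(1, x, yn, "continuous")) > 0
  }, TRUE)
  expect_gt(binom.test(sum(hits), 400, 0.05)$p.value, 0.001)

  # lasso-mode validation restricts to the selected columns
  vl <- validate_selection(c(2, 5, 6), x, y, "continuous", mode = "lasso",
                           seed = 3)
  expect_true(all(vl %in% c(2, 5, 6)))
  expect_true(2 %in% vl)

  # selection_result round trip fills the validated field
  r <- univ_screen(x, y, "continuous", p_threshold = 0.05)
  r <- validate_selection(r, x, y, "continuous")
  expect_true(all(r$validated %in% r$selected))
  expect_false(any(is.na(tidy(r)$validated)))
})
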