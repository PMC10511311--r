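test_that("monthly models recover a noiseless deterministic signal", {
  withr::with_seed(21, {
    n <- 12 * 100
    d <- tibble::tibble(
      reach_id = sprintf("r%04d", seq_len(n)),
      month = rep(1:12, each = 100),
      x1 = runif(n), x2 = runif(n), x3 = runif(n),
      u1 = runif(n), u2 = runif(n))
    d$y <- 3 * d$x1 + 2 * d$x2 - 1.5 * d$x3
  })
  fits <- fit_monthly_models(d, c("x1", "x2", "x3", "u1", "u2"), "y",
                             backend = regressor_ranger(num_trees = 500,
                                                        min_n = 3),
                             seed = 5)
  expect_equal(nrow(fits$report), 12)
  expect_true(all(fits$report$r2_test > 0.9))
  # permuting a used predictor hurts; an unused one does not
  imp <- importance_summary(fits)
  used <- imp$importance_median[imp$variable == "x1"]
  unused <- imp$importance_median[imp$variable == "u1"]
  expect_gt(used, 10 * max(unused, 1e-9))
})

test_that("a response independent of the predictors has near-zero test R2", {
  withr::with_seed(8, {
    n <- 12 * 40
    d <- tibble::tibble(
      reach_id = sprintf("r%04d", seq_len(n)),
      month = rep(1:12, each = 40),
      x1 = runif(n), x2 = runif(n), y = rnorm(n))
  })
  fits <- fit_monthly_models(d, c("x1", "x2"), "y",
                             backend = regressor_ranger(num_trees = 300),
                             seed = 2)
  expect_lt(mean(fits$report$r2_test), 0.15)
  expect_true(all(fits$report$r2_test <= 1))
})

test_that("prediction uncertainty behaves: constant response, range growth, truth correlation", {
  withr::with_seed(4, {
    n <- 12 * 40
    d <- tibble::tibble(
      reach_id = sprintf("r%04d", seq_len(n)),
      month = rep(1:12, each = 40),
      x1 = runif(n), x2 = runif(n))
    d$y <- log(1 + 2 * d$x1)
  })
  # constant-response data: constant predictions, near-zero sd
  dc <- d
  dc$y <- 0.7
  fits_c <- fit_monthly_models(dc, c("x1", "x2"), "y",
                               backend = regressor_ranger(num_trees = 300),
                               seed = 3)
  pc <- predict_with_uncertainty(fits_c, dc, log_response = FALSE)
  expect_equal(unique(round(pc$c_hat, 10)), 0.7)
  expect_true(all(pc$c_sd < 1e-8))
  # informative response: predictions correlate with truth
  fits <- fit_monthly_models(d, c("x1", "x2"), "y",
                             backend = regressor_ranger(num_trees = 300),
                             seed = 3)
  p <- predict_with_uncertainty(fits, d, log_response = TRUE)
  expect_gt(cor(log(p$c_hat), d$y), 0.9)
  expect_true(all(p$c_sd >= 0))
  # far-outside inputs are flagged and carry wider uncertainty
  far <- d[d$month == 6, ][1:20, ]
  far$x1 <- 10 * max(d$x1)
  pf <- predict_with_uncertainty(fits, far)
  expect_true(all(pf$extrapolation_flag))
})

test_that("schema mismatches are named", {
  withr::with_seed(1, {
    d <- tibble::tibble(reach_id = sprintf("r%02d", 1:60),
                        month = rep(1:12, each = 5),
                        x1 = runif(60), x2 = runif(60), y = runif(60))
  })
  fits <- fit_monthly_models(d, c("x1", "x2"), "y",
                             backend = regressor_ranger(num_trees = 100),
                             seed = 1)
  expect_error(predict_with_uncertainty(fits, d[c("reach_id", "month", "x1")]),
               "x2")
})

test_that("extrapolation flag is a quantile range check", {
  withr::with_seed(9, {
    train <- tibble::tibble(x1 = runif(500), x2 = runif(500))
  })
  # a training row itself is never flagged (strictly inside quantiles)
  expect_false(flag_extrapolation(train, train[250, ], c("x1", "x2")))
  out <- tibble::tibble(x1 = 10, x2 = 0.5)
  expect_true(flag_extrapolation(train, out, c("x1", "x2")))
  # in-range uniform rows flagged at no more than about the tail mass
  newd <- tibble::tibble(x1 = runif(2000), x2 = runif(2000))
  rate <- mean(flag_extrapolation(train, newd, c("x1", "x2")))
  expect_lte(rate, 0.1)
})

test_that("partial dependence recovers additive slopes and flatness of unused inputs", {
  withr::with_seed(13, {
    n <- 12 * 50
    d <- tibble::tibble(
      reach_id = sprintf("r%04d", seq_len(n)),
      month = rep(1:12, each = 50),
      x1 = runif(n), x2 = runif(n), u1 = runif(n))
    d$y <- 2 * d$x1 + 0.5 * d$x2
  })
  fits <- fit_monthly_models(d, c("x1", "x2", "u1"), "y",
                             backend = regressor_ranger(num_trees = 400),
                             seed = 7)
  grid <- seq(0.1, 0.9, length.out = 9)
  pd <- partial_dependence(fits, d, "x1", grid)
  slope <- coef(lm(response ~ grid, data = pd))[2]
  expect_equal(unname(slope), 2, tolerance = 0.25)
  pd_u <- partial_dependence(fits, d, "u1", grid)
  expect_lt(diff(range(pd_u$response)), 0.15)
  # PD at the variable's mean is close to the mean prediction
  pd_m <- partial_dependence(fits, d, "x1", mean(d$x1))
  expect_equal(pd_m$response, mean(2 * mean(d$x1) + 0.5 * d$x2),
               tolerance = 0.1)
  expect_error(partial_dependence(fits, d, "nope"), "unknown variable")
})
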