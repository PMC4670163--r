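test_that("sliding-window noise variance matches hand calculations", {
  expect_equal(estimate_noise_variance(rep(3.7, 30)), 0)
  # alternating +1/-1, n = 20, window 10: every window holds five of
  # each sign, variance 10/9
  expect_equal(estimate_noise_variance(rep(c(1, -1), 10)), 10 / 9)
  expect_error(estimate_noise_variance(c(1, 2)), "at least 3")
  expect_warning(v <- estimate_noise_variance(rnorm(6)), "single window")
  withr::local_seed(8)
  est <- replicate(10, estimate_noise_variance(rnorm(200)))
  expect_lt(abs(mean(est) - 1), 0.1)
  expect_true(all(est > 0.6 & est < 1.4))
})

test_that("an exact cubic needs zero knots and leaves zero residuals", {
  ages <- sample_ages(60, seed = 9)
  x <- log2(ages)
  y <- 0.05 * x^3 - 0.8 * x^2 + 2 * x + 1
  fit <- fit_trend_spline(make_profile(ages, y), sigma2_hat = 0.5)
  expect_equal(fit$n_knots, 0)
  expect_lt(fit$mse, 1e-20)
  expect_false(fit$relaxed)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-9)
})

test_that("trend fitting validates degenerate designs", {
  expect_error(fit_trend_spline(make_profile(rep(100, 10), rnorm(10))),
               "degenerate")
  expect_error(fit_trend_spline(make_profile(1:5 * 100, rnorm(5))),
               "at least 8")
})

test_that("in-sample MSE decreases along the knot sequence", {
  # quantile-placed knots are not nested, so tiny local increases are
  # possible; the sequence must still be decreasing overall and any
  # increase must be small relative to the fit scale
  withr::local_seed(13)
  ages <- sample_ages(80, seed = 13)
  y <- sin(log2(ages)) + rnorm(80, 0, 0.3)
  prof <- make_profile(ages, y)
  mses <- vapply(0:6, function(k)
    fit_trend_spline(prof, n_knots = k)$mse, numeric(1))
  expect_lt(mses[7], mses[1])
  expect_true(all(diff(mses) <= 0.02 * mses[1]))
})

test_that("residuals are orthogonal to the fitted basis", {
  withr::local_seed(14)
  ages <- sample_ages(70, seed = 14)
  y <- rnorm(70, 6, 0.5)
  prof <- make_profile(ages, y)
  fit <- fit_trend_spline(prof, n_knots = 2)
  # residuals centre on zero (intercept in the basis)
  expect_lt(abs(mean(residuals(fit))), 1e-8 * sd(y))
  # adding a function representable in the k-knot basis leaves residuals
  # unchanged: here a quadratic plus a multiple of the fitted curve
  x <- log2(ages)
  prof2 <- make_profile(ages, y + 2.5 * fitted(fit) + 0.1 * x^2)
  fit2 <- fit_trend_spline(prof2, n_knots = 2)
  expect_equal(residuals(fit2), residuals(fit), tolerance = 1e-8)
})

test_that("the relaxed flag fires only when the noise bound is unsatisfiable", {
  withr::local_seed(15)
  ages <- sample_ages(40, seed = 15)
  y <- rnorm(40, 6, 1)
  prof <- make_profile(ages, y)
  ok <- fit_trend_spline(prof)             # honest sigma2: satisfiable
  expect_false(ok$relaxed)
  # an impossibly small tolerance cannot be met at any knot count
  expect_warning(bad <- fit_trend_spline(prof, sigma2_hat = 1e-12,
                                         max_knots = 3),
                 "unsatisfiable")
  expect_true(bad$relaxed)
  # a tolerance met only after doubling sets the flag without warning
  k0 <- fit_trend_spline(prof, n_knots = 0)
  mid <- fit_trend_spline(prof, sigma2_hat = k0$mse / 1.5, max_knots = 0)
  expect_true(mid$relaxed)
  expect_equal(mid$n_knots, 0)
})

test_that("pure noise selects a small knot count most of the time", {
  withr::local_seed(16)
  ks <- vapply(1:30, function(i) {
    ages <- sample_ages(100, seed = 1600 + i)
    fit_trend_spline(make_profile(ages, rnorm(100)))$n_knots
  }, numeric(1))
  expect_gte(mean(ks <= 2), 0.85)
})

test_that("detrending recovers planted noise around a smooth trend", {
  tf <- trend_function("logistic", baseline = 6, amplitude = 3)
  withr::local_seed(17)
  ages <- sample_ages(200, seed = 17)
  noise <- rnorm(200, 0, 0.4)
  det <- detrend(make_profile(ages, tf$fn(ages) + noise))
  expect_equal(names(det)[7:8], c("fitted", "residual"))
  expect_lt(abs(var(det$residual) / 0.16 - 1), 0.25)
  # a constant offset is absorbed by the intercept
  det2 <- detrend(make_profile(ages, tf$fn(ages) + noise + 4.2))
  expect_equal(det2$residual, det$residual, tolerance = 1e-8)
  # a profile equal to its own fitted trend has zero residuals when the
  # same basis is used (knot re-selection may legitimately pick a
  # smoother basis whose window-estimated tolerance it satisfies)
  k_used <- fit_trend_spline(make_profile(ages, tf$fn(ages) + noise))$n_knots
  refit <- detrend(make_profile(ages, det$fitted), n_knots = k_used)
  expect_lt(max(abs(refit$residual)), 1e-8)
})

test_that("leave-one-out R^2 separates trend from shuffled data", {
  withr::local_seed(18)
  ages <- sample_ages(60, seed = 18)
  x <- log2(ages)
  strong <- (x - mean(x)) / sd(x) * 2 + rnorm(60, 0, 0.05)
  r2 <- loo_r2(make_profile(ages, strong))
  expect_gt(r2, 0.95)
  expect_lte(r2, 1)
  shuffled <- loo_r2(make_profile(ages, sample(strong)))
  expect_lt(shuffled, 0.3)
  expect_true(is.na(loo_r2(make_profile(ages, rep(2, 60)))))
  expect_error(loo_r2(make_profile(ages[1:8], strong[1:8])), "at least 10")
})

test_that("tidy and glance summarise a trend fit", {
  ages <- sample_ages(50, seed = 19)
  tf <- trend_function("logistic")
  prof <- make_profile(ages, tf$fn(ages) + rnorm(50, 0, 0.3), gene = "GRIN2B")
  fit <- fit_trend_spline(prof)
  td <- tidy(fit)
  expect_equal(nrow(td), 50)
  expect_equal(td$value - td$fitted, td$residual)
  gl <- glance(fit)
  expect_equal(gl$gene, "GRIN2B")
  expect_equal(gl$mse, fit$mse)
})
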