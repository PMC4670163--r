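test_that("partial correlation matches the regression-residual route", {
  withr::local_seed(31)
  for (i in 1:10) {
    z <- rnorm(60)
    x <- 0.8 * z + rnorm(60, 0, 0.6)
    y <- -0.5 * z + rnorm(60, 0, 0.8)
    expect_equal(partial_correlation(x, y, z),
                 cor(resid(lm(x ~ z)), resid(lm(y ~ z))),
                 tolerance = 1e-12)
  }
  # closed form at r_xy = 0.5, r_xz = r_yz = 0.8:
  # (0.5 - 0.64) / 0.36 = -0.38889
  expect_equal((0.5 - 0.8 * 0.8) / sqrt((1 - 0.64) * (1 - 0.64)), -7 / 18)
  z <- rnorm(30)
  expect_error(partial_correlation(rnorm(30), z, z), "collinear")
  expect_error(partial_correlation(1:3, 1:3, 3:1), "at least 4")
})

test_that("partial correlation given an irrelevant covariate equals the raw one", {
  withr::local_seed(32)
  n <- 10000
  x <- rnorm(n); y <- 0.4 * x + rnorm(n); z <- rnorm(n)
  expect_lt(abs(partial_correlation(x, y, z) - cor(x, y)), 0.05)
})

test_that("identical profiles have unit residual correlation", {
  ages <- sample_ages(50, seed = 33)
  tf <- trend_function("logistic")
  withr::local_seed(33)
  p <- make_profile(ages, tf$fn(ages) + rnorm(50, 0, 0.3), gene = "A")
  q <- dplyr::mutate(p, gene = "B")
  ac <- age_corrected_correlation(p, q)
  expect_equal(ac$summary$resid_rho, 1)
  expect_equal(ac$summary$trend_corr, 1)
})

test_that("a shared subject factor reverses the sign after age correction", {
  sp <- switch_pair_spec()   # anti-correlated logistic trends, target 0.5
  ages <- sample_ages(100, seed = 34)
  sim <- simulate_switch_pair(sp, ages, seed = 134)
  ac <- age_corrected_correlation(sim$x, sim$y)
  expect_lt(ac$summary$raw_rho, 0)
  expect_gt(ac$summary$resid_rho, 0.3)
  expect_lt(ac$summary$trend_corr, -0.9)
})

test_that("without a shared factor residual correlation is null-calibrated", {
  sp <- switch_pair_spec(shared_factor_sd = 0)
  ages <- sample_ages(100, seed = 35)
  ps <- vapply(1:20, function(i) {
    sim <- simulate_switch_pair(sp, ages, seed = 3500 + i)
    ac <- age_corrected_correlation(sim$x, sim$y)
    c(ac$summary$resid_rho, ac$summary$resid_p)
  }, numeric(2))
  expect_true(all(abs(ps[1, ]) < 0.35))
  expect_gte(mean(ps[2, ] > 0.01), 0.9)
})

test_that("the linear trend basis reproduces the partial correlation exactly", {
  withr::local_seed(36)
  n <- 120
  ages <- sort(runif(n, 100, 25000))
  u <- rnorm(n, 0, 0.5)
  x <- make_profile(ages, 5 + ages / 8000 + u + rnorm(n, 0, 0.5), gene = "A")
  y <- make_profile(ages, 9 - ages / 8000 + u + rnorm(n, 0, 0.5), gene = "B")
  ac <- age_corrected_correlation(x, y, age_transform = "linear",
                                  degree = 1, n_knots = 0)
  expect_equal(ac$summary$resid_rho,
               partial_correlation(x$value, y$value, ages),
               tolerance = 1e-6)
})

test_that("trend and residual correlations are affine-invariant separately", {
  sp <- switch_pair_spec()
  ages <- sample_ages(80, seed = 37)
  sim <- simulate_switch_pair(sp, ages, seed = 137)
  base <- age_corrected_correlation(sim$x, sim$y)$summary
  scaled <- dplyr::mutate(sim$y, value = 2.7 * value + 3)
  up <- age_corrected_correlation(sim$x, scaled)$summary
  expect_equal(up$trend_corr, base$trend_corr, tolerance = 1e-8)
  expect_equal(up$resid_rho, base$resid_rho, tolerance = 1e-8)
})

test_that("trend anti-correlation does not imply residual correlation", {
  ages <- sample_ages(400, seed = 38)
  coupled <- simulate_switch_pair(switch_pair_spec(), ages, seed = 380)
  uncoupled <- simulate_switch_pair(switch_pair_spec(shared_factor_sd = 0),
                                    ages, seed = 381)
  ac1 <- age_corrected_correlation(coupled$x, coupled$y)$summary
  ac2 <- age_corrected_correlation(uncoupled$x, uncoupled$y)$summary
  expect_lt(ac1$trend_corr, -0.9)
  expect_gt(ac1$resid_rho, 0.4)
  expect_lt(ac2$trend_corr, -0.9)
  expect_lt(abs(ac2$resid_rho), 0.1)
})

test_that("age windows restrict the samples and refit inside", {
  sp <- switch_pair_spec()
  ages <- sample_ages(150, seed = 39)
  sim <- simulate_switch_pair(sp, ages, seed = 139)
  pre <- age_corrected_correlation(sim$x, sim$y, age_window = c(70, 280))
  expect_equal(pre$summary$n_samples, sum(ages >= 70 & ages <= 280))
  expect_equal(pre$summary$age_hi, 280)
  expect_error(
    age_corrected_correlation(sim$x, sim$y, age_window = c(70, 80)),
    "fewer than 8")
})

test_that("pairs are ranked by mean score over their tested regions", {
  tbl <- tibble::tribble(
    ~gene_a, ~gene_b, ~region, ~q_value,
    "A", "B", "R1", 1e-4,
    "A", "B", "R2", 1e-2,
    "C", "D", "R1", 1e-3,
    "C", "D", "R2", NA_real_,   # filtered region: excluded from the mean
    "A", "C", "R1", 1e-3,
    "A", "C", "R2", 1e-3)
  rk <- rank_pairs(tbl)
  expect_equal(rk$mean_score, c(3, 3, 3))
  # ties break lexicographically: (A,B) before (A,C) before (C,D)
  expect_equal(rk$gene_a, c("A", "A", "C"))
  expect_equal(rk$gene_b, c("B", "C", "D"))
  expect_equal(rk$n_regions, c(2L, 2L, 1L))
  expect_equal(rk$rank, 1:3)
  one <- rank_pairs(tbl[tbl$region == "R1", ])
  expect_equal(one$gene_a[1], "A")
  expect_equal(one$mean_score[1], 4)
})
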