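test_that("EONR solves the marginal-return equation analytically", {
  d <- quad_data(a = 4000, b = 50, c = -0.09)
  f <- fit_quadratic(d$n_rate, d$yield)
  est <- eonr(f, max_rate = 350)
  expect_equal(est$eonr, (5.6 - 50) / (2 * -0.09), tolerance = 1e-6)  # 246.67
  expect_equal(est$yeonr, predict(f, n_rate = est$eonr), tolerance = 1e-9)
  expect_equal(est$boundary, "interior")
})

test_that("boundary flags cover zero, max-rate censoring and undefined fits", {
  # marginal value at the origin equals the fertilizer cost -> optimum 0
  d0 <- quad_data(a = 4000, b = 5.6, c = -0.09)
  e0 <- eonr(fit_quadratic(d0$n_rate, d0$yield))
  expect_equal(e0$eonr, 0)
  expect_equal(e0$boundary, "at_zero")

  # optimum beyond the tested range is censored, not extrapolated
  dmax <- quad_data(a = 3000, b = 60, c = -0.05)  # unconstrained 544
  emax <- eonr(fit_quadratic(dmax$n_rate, dmax$yield))
  expect_equal(emax$eonr, 268)
  expect_equal(emax$boundary, "at_max")

  # convex or non-converged fits give undefined estimates, not errors
  f <- fit_quadratic(d0$n_rate, d0$yield); f$c <- 0.01
  expect_equal(eonr(f)$boundary, "undefined")
  expect_true(is.na(eonr(NULL)$eonr))
})

test_that("plateau EONR is capped at the join point", {
  d <- qp_data(a = 4000, b = 50, x0 = 150)   # c = -1/6
  f <- fit_quadratic_plateau(d$n_rate, d$yield)
  # unconstrained root (5.6 - 50) / (2 * -1/6) = 133.2 lies below x0
  est <- eonr(f, max_rate = 350)
  expect_equal(est$eonr, (5.6 - 50) / (2 * (-50 / 300)), tolerance = 0.3)
  # with a zero price ratio the slope never reaches the threshold before x0
  est0 <- eonr(f, econ_config(price_ratio = 1e-9), max_rate = 350)
  expect_equal(est0$eonr, f$x0, tolerance = 1e-6)
})

test_that("EONR equals dense numeric profit maximization and falls with price", {
  set.seed(5)
  prev <- Inf
  for (ratio in c(2, 5.6, 10)) {
    d <- quad_data(a = 4200, b = 55, c = -0.11)
    f <- fit_quadratic(d$n_rate, d$yield)
    est <- eonr(f, econ_config(ratio), max_rate = 400)
    oracle <- numeric_eonr(function(n) predict(f, n_rate = n), ratio, 400)
    expect_equal(est$eonr, oracle, tolerance = 0.01)
    expect_lte(est$eonr, prev)   # non-increasing in the price ratio
    prev <- est$eonr
  }
})

test_that("return-to-N scan finds the optimum within one grid step", {
  d <- quad_data(a = 4000, b = 50, c = -0.09)
  f <- fit_quadratic(d$n_rate, d$yield)
  grid <- seq(0, 350, 5)
  est <- rtn_optimum(grid, predict(f, n_rate = grid))
  expect_equal(est$eonr, 245)   # analytic 246.7, one 5-kg step below
  expect_lte(abs(est$eonr - 246.67), 5)
  expect_equal(attr(est, "discrepancy"), 0)

  # flat curve: no response, optimum at zero
  flat <- rtn_optimum(grid, rep(9000, length(grid)))
  expect_equal(flat$eonr, 0)
  expect_equal(flat$boundary, "at_zero")

  # curve still rising at the economic margin at the top of the grid
  rising <- rtn_optimum(grid, 4000 + 20 * grid)
  expect_equal(rising$boundary, "at_max")

  expect_error(rtn_optimum(c(0, 5, 20), c(1, 2, 3)), "uniformly spaced")
  expect_error(rtn_optimum(c(5, 0, 10), c(1, 2, 3)), "increasing")
})

test_that("RTN on fitted concave curves stays within one step of the analytic EONR", {
  set.seed(13)
  grid <- seq(0, 350, 5)
  for (i in 1:20) {
    b <- runif(1, 20, 70); c <- -runif(1, 0.05, 0.2)
    d <- quad_data(a = runif(1, 2000, 6000), b = b, c = c, rates = grid)
    f <- fit_quadratic(d$n_rate, d$yield)
    analytic <- eonr(f, max_rate = 350)
    scan <- rtn_optimum(grid, predict(f, n_rate = grid))
    if (analytic$boundary == "interior")
      expect_lte(abs(scan$eonr - analytic$eonr), 5)
  }
})

test_that("across-years site mean averages defined years only", {
  ests <- list(
    optimum_estimate(100, 9000, year = 2001, rotation = "CC"),
    optimum_estimate(200, 9500, year = 2002, rotation = "CC"),
    optimum_estimate(NA, method = "regression_eonr", boundary = "undefined"))
  sm <- site_mean(ests, "across_years")
  expect_equal(sm$mean_eonr, 150)
  expect_equal(sm$sd_eonr, sd(c(100, 200)), tolerance = 1e-10)  # 70.7
  expect_equal(sm$n_years, 2)

  # identical yearly estimates -> zero SD
  same <- list(optimum_estimate(150, 9000), optimum_estimate(150, 9000))
  expect_equal(site_mean(same, "across_years")$sd_eonr, 0)

  # nothing defined -> undefined result
  none <- list(optimum_estimate(NA, boundary = "undefined"))
  expect_equal(site_mean(none, "across_years")$boundary, "undefined")
})

test_that("pooled site mean equals the hand-chained mean-response fit", {
  ex <- generate_experiment(16, seed = 101)
  cc <- ex$trial[ex$trial$rotation == "CC" & ex$trial$crop == "corn", ]
  sm <- site_mean(cc, "pooled")

  # oracle: average yields per rate across years, then fit -> select -> eonr
  means <- aggregate(yield ~ n_rate, cc, mean)
  fit <- fit_group(means$n_rate, means$yield, level = "mean")
  oracle <- eonr(fit, max_rate = max(means$n_rate))
  expect_equal(sm$mean_eonr, oracle$eonr, tolerance = 1e-9)
  expect_equal(sm$mean_yeonr, oracle$yeonr, tolerance = 1e-9)
  expect_true(is.na(sm$sd_eonr))

  # invariant to year ordering
  perm <- cc[order(-cc$year, cc$n_rate), ]
  expect_equal(site_mean(perm, "pooled")$mean_eonr, sm$mean_eonr,
               tolerance = 1e-9)
})

test_that("across-years and pooled agree on identical noiseless years", {
  d <- quad_data(a = 4000, b = 50, c = -0.09, reps = 1)
  tt <- do.call(rbind, lapply(2001:2004, function(yr)
    data.frame(year = yr, rotation = "CC", crop = "corn",
               n_rate = d$n_rate, rep = 1, yield = d$yield)))
  tt <- as_trial_table(tt)
  yearly <- estimate_yearly_optima(tt)
  ests <- lapply(seq_len(nrow(yearly)), function(i)
    optimum_estimate(yearly$eonr[i], yearly$yeonr[i],
                     boundary = yearly$boundary[i]))
  ay <- site_mean(ests, "across_years")
  pl <- site_mean(tt, "pooled")
  expect_equal(ay$mean_eonr, pl$mean_eonr, tolerance = 1e-6)
  expect_equal(ay$sd_eonr, 0, tolerance = 1e-6)
})

test_that("method differences are exact signed subtractions with NA propagation", {
  obs <- optimum_estimate(187, 11000, rotation = "CC")
  unc <- optimum_estimate(226, 11200, rotation = "CC")
  expect_equal(method_difference(obs, unc), -39)
  expect_equal(method_difference(obs, obs), 0)
  undef <- optimum_estimate(NA, boundary = "undefined")
  expect_true(is.na(method_difference(obs, undef)))
  expect_error(method_difference(obs, 42), "operands")
})
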