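test_that("window sums are inclusive, calendar-aware and additive", {
  mk_year <- function(yr, value) {
    days <- seq(as.Date(paste0(yr, "-01-01")), as.Date(paste0(yr, "-12-31")),
                by = "day")
    data.frame(year = yr, date = days, precip = value)
  }
  spring <- precip_window("apr_jun", "04-01", "06-30")
  expect_equal(window_sum(mk_year(2003, 2), spring), 182)   # 91 days x 2 mm
  expect_equal(window_sum(mk_year(2004, 2), spring), 182)   # leap year: unchanged
  expect_equal(window_sum(mk_year(2003, 0), spring), 0)

  # additive over disjoint windows covering the same span
  d <- mk_year(2003, 1)
  d$precip <- runif(nrow(d))
  apr <- window_sum(d, precip_window("apr", "04-01", "04-30"))
  may_jun <- window_sum(d, precip_window("may_jun", "05-01", "06-30"))
  expect_equal(apr + may_jun, window_sum(d, spring), tolerance = 1e-12)

  short <- mk_year(2003, 1)[100:120, ]
  expect_error(window_sum(short, spring), "cover")
  expect_error(precip_window("bad", "06-30", "04-01"), "start")
})

test_that("simple regression recovers exact lines and matches closed form", {
  x <- 1:10
  # summary.lm flags the zero-residual fit as "essentially perfect"
  r <- suppressWarnings(simple_regression(x, 2 * x + 1))
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$intercept, 1, tolerance = 1e-12)
  expect_equal(r$r2, 1, tolerance = 1e-12)

  flat <- simple_regression(x, rep(5, 10))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$r2, 0, tolerance = 1e-12)

  set.seed(41)
  xs <- rnorm(60); ys <- 3 - 1.7 * xs + rnorm(60, 0, 0.5)
  r2 <- simple_regression(xs, ys)
  # closed-form normal equations oracle
  sl <- cov(xs, ys) / var(xs)
  ic <- mean(ys) - sl * mean(xs)
  expect_equal(r2$slope, sl, tolerance = 1e-10)
  expect_equal(r2$intercept, ic, tolerance = 1e-10)
  expect_equal(r2$r2, cor(xs, ys)^2, tolerance = 1e-10)

  degen <- simple_regression(rep(3, 5), rnorm(5))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$slope))
  expect_error(simple_regression(1:2, 1:2), ">= 3")
})

test_that("regression R2 is invariant to affine rescaling of both variables", {
  set.seed(43)
  x <- runif(30); y <- 1 + 2 * x + rnorm(30, 0, 0.3)
  r <- simple_regression(x, y)
  r_scaled <- simple_regression(10 * x - 4, -0.3 * y + 7)
  expect_equal(r$r2, r_scaled$r2, tolerance = 1e-10)
})

test_that("window screening ranks by R2, matches single regression, drops NA years", {
  ex <- generate_experiment(16, seed = 55)
  daily <- simulate_daily_precip(ex$weather, seed = 56)
  cc <- ex$truth[ex$truth$rotation == "CC", ]
  eonr_df <- data.frame(year = cc$year, eonr = cc$true_eonr)

  one <- screen_windows(daily, eonr_df,
                        windows = list(precip_window("apr_jun", "04-01",
                                                     "06-30")))
  sums <- vapply(sort(unique(eonr_df$year)), function(yr)
    window_sum(daily[daily$year == yr, ],
               precip_window("apr_jun", "04-01", "06-30")), numeric(1))
  direct <- simple_regression(sums, eonr_df$eonr[order(eonr_df$year)])
  expect_equal(one$r2, direct$r2, tolerance = 1e-10)
  expect_equal(one$slope, direct$slope, tolerance = 1e-10)

  full <- screen_windows(daily, eonr_df)
  expect_true(all(diff(full$r2) <= 1e-12))     # ranked descending

  # undefined years are dropped pairwise with n reported
  eonr_na <- eonr_df; eonr_na$eonr[1:3] <- NA
  scr <- screen_windows(daily, eonr_na,
                        windows = list(precip_window("apr_jun", "04-01",
                                                     "06-30")))
  expect_equal(scr$n, 13)
})

test_that("the spring window dominates the silking window on generator output", {
  wins <- vapply(1:20, function(s) {
    ex <- generate_experiment(16, seed = 2000 + s)
    daily <- simulate_daily_precip(ex$weather, seed = 3000 + s)
    cc <- ex$truth[ex$truth$rotation == "CC", ]
    scr <- screen_windows(daily, data.frame(year = cc$year,
                                            eonr = cc$true_eonr),
                          windows = list(
                            precip_window("apr_jun", "04-01", "06-30"),
                            precip_window("jul_silking", "07-01", "07-31")))
    scr$label[1] == "apr_jun"
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("carryover check is null on generator soybeans, detects a planted signal", {
  hits <- vapply(1:50, function(s) {
    ex <- generate_experiment(4, seed = 4000 + s)
    soy <- ex$trial[ex$trial$crop == "soybean", ]
    carryover_check(soy$yield, soy$n_rate)$p_value < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.10)    # type-I error near the nominal 5%

  set.seed(91)
  n <- rep(trial_rates, each = 8)
  planted <- 3000 + 5 * n + rnorm(length(n), 0, 10)
  sig <- carryover_check(planted, n)
  expect_lt(sig$p_value, 1e-6)
  expect_equal(sig$slope, 5, tolerance = 0.05)

  flat <- carryover_check(rep(3400, 20), rep(trial_rates, 4))
  expect_equal(flat$slope, 0, tolerance = 1e-10)
})

test_that("multi-factor regression is a plain descriptive OLS", {
  ex <- generate_experiment(16, seed = 61)
  cc <- merge(ex$truth[ex$truth$rotation == "CC", ], ex$weather)
  d <- data.frame(eonr = cc$true_eonr, spring = cc$spring_precip,
                  yeonr = cc$true_yeonr)
  fit <- multi_factor_regression(d, c("spring", "yeonr"))
  expect_s3_class(fit, "lm")
  expect_equal(length(coef(fit)), 3L)
  expect_error(multi_factor_regression(d, "nope"), "predictors")
})

test_that("daily disaggregation reproduces the seasonal sums exactly", {
  w <- simulate_weather(3, seed = 71)
  daily <- simulate_daily_precip(w, seed = 72)
  for (i in 1:3) {
    dyr <- daily[daily$year == w$year[i], ]
    expect_equal(window_sum(dyr, precip_window("apr_jun", "04-01", "06-30")),
                 w$spring_precip[i], tolerance = 1e-9)
    expect_equal(window_sum(dyr, precip_window("jul", "07-01", "07-31")),
                 w$silking_precip[i], tolerance = 1e-9)
    expect_equal(sum(dyr$precip), w$annual_precip[i], tolerance = 1e-9)
  }
  expect_true(all(daily$precip >= 0))
})
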