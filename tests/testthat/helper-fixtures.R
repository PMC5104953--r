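# Shared fixture builders for the suite.

trial_rates <- c(0, 67, 134, 201, 268)

# Exact quadratic yields at the trial rates, optionally replicated.
quad_data <- function(a = 4000, b = 50, c = -0.09, reps = 4,
                      rates = trial_rates) {
  d <- data.frame(n_rate = rep(rates, each = reps),
                  rep = rep(seq_len(reps), times = length(rates)))
  d$yield <- a + b * d$n_rate + c * d$n_rate^2
  d
}

# Exact smooth quadratic-plateau yields (join point x0 = -b/(2c)).
qp_data <- function(a = 4000, b = 50, x0 = 150, reps = 4,
                    rates = trial_rates) {
  c <- -b / (2 * x0)
  xx <- pmin(rates, x0)
  d <- data.frame(n_rate = rep(rates, each = reps))
  d$yield <- rep(a + b * xx + c * xx^2, each = reps)
  d
}

# Minimal valid trial data.frame in canonical kg/ha.
toy_trial <- function() {
  d <- quad_data(reps = 2)
  as_trial_table(data.frame(year = 2001, rotation = "CC", crop = "corn",
                            n_rate = d$n_rate, rep = d$rep, yield = d$yield))
}

# Brute-force normal-equations quadratic solve (independent of lm).
normal_eq_quadratic <- function(x, y) {
  X <- cbind(1, x, x^2)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Dense numeric profit maximizer over [0, nmax]: argmax Y(N) - ratio * N.
numeric_eonr <- function(yield_fun, ratio, nmax, step = 0.01) {
  grid <- seq(0, nmax, by = step)
  profit <- yield_fun(grid) - ratio * grid
  grid[which.max(profit)]
}
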