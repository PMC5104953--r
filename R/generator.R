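#' Parameters of the synthetic trial generator
#'
#' Full parameterization of the weather-to-N-to-yield process used to
#' generate multi-year, two-rotation, replicated N-rate trials with known
#' ground truth. The mechanism composes four pieces: (1) rotation-dependent
#' soil N supply that declines linearly with spring precipitation above a
#' reference; (2) a fertilizer-loss fraction that rises exponentially with
#' spring precipitation (denitrification plus leaching); (3) a
#' quadratic-plateau expected-yield response in plant-available N
#' (supply + recovered fertilizer); (4) multiplicative year and replicate
#' noise. Atmospheric N deposition enters the supply term. The true economic
#' optimum has a closed form (see [true_optimum()]), which is what makes the
#' generator useful for parameter-recovery testing.
#'
#' @param y0 base yield intercept at zero available N, kg/ha.
#' @param b_av linear yield response to available N, kg grain per kg N.
#' @param c_av curvature in available N (negative), kg grain per (kg N)^2.
#' @param s0_cc mean continuous-corn soil N supply at reference
#'   precipitation, kg N/ha.
#' @param sc_supply_factor soybean-corn supply multiplier (rotation credit);
#'   1.5 makes SC supply 50% higher than CC.
#' @param supply_precip_slope fractional supply change per mm of spring
#'   precipitation above `precip_ref` (negative: wet springs mineralize
#'   less into the usable pool); floored at a factor 0.5.
#' @param loss_base fertilizer-loss fraction at reference precipitation.
#' @param loss_exp_rate exponential rate of loss increase per mm of spring
#'   precipitation above `precip_ref`; the fraction is capped at `loss_cap`.
#' @param loss_cap upper bound on the loss fraction.
#' @param precip_ref reference spring precipitation, mm.
#' @param year_effect_cv CV of the multiplicative year factor
#'   (truncated at 0.4 so yields stay positive).
#' @param rep_cv CV of multiplicative replicate noise.
#' @param deposition_coeff atmospheric N deposition per mm precipitation,
#'   kg N/ha per mm.
#' @param price_ratio break-even kg grain per kg N, used for the true optima.
#' @param n_rates fertilizer treatments, kg N/ha.
#' @param n_reps replicates per treatment.
#' @param soy_mean,soy_sd soybean yield distribution (kg/ha), independent of
#'   the N applied to the prior corn crop.
#' @return object of class `generator_params`.
#' @export
generator_params <- function(y0 = 2000, b_av = 85, c_av = -0.16,
                             s0_cc = 80, sc_supply_factor = 1.5,
                             supply_precip_slope = -0.0005,
                             loss_base = 0.08, loss_exp_rate = 0.004,
                             loss_cap = 0.8, precip_ref = 400,
                             year_effect_cv = 0.13, rep_cv = 0.08,
                             deposition_coeff = 0.01, price_ratio = 5.6,
                             n_rates = c(0, 67, 134, 201, 268), n_reps = 4,
                             soy_mean = 3400, soy_sd = 660) {
  stopifnot(c_av < 0, loss_base >= 0, loss_base < 1, loss_cap < 1,
            year_effect_cv >= 0, rep_cv >= 0, price_ratio > 0)
  structure(as.list(environment()), class = "generator_params")
}

#' Simulate seasonal weather for a trial site
#'
#' Draws yearly precipitation totals for a rainfed site with ~900 mm mean
#' annual precipitation: annual ~ Normal(900, 180) clipped to [550, 1300] mm;
#' spring (Apr 1 - Jun 30 window sum) ~ Normal(400, 90) clipped to
#' [150, min(700, annual)]; silking window (July, 15 days either side of
#' silking) ~ Normal(110, 45) clipped to [0, annual - spring].
#'
#' @param n_years number of years.
#' @param params a [generator_params()] (reserved for future weather knobs).
#' @param seed optional integer; the draw is reproducible per seed and global
#'   RNG state is restored.
#' @param start_year first calendar year label.
#' @return data.frame `year`, `annual_precip`, `spring_precip`,
#'   `silking_precip` (mm).
#' @export
simulate_weather <- function(n_years, params = generator_params(),
                             seed = NULL, start_year = 2001L) {
  stopifnot(n_years >= 1)
  with_seed(seed, {
    annual <- pmin(pmax(stats::rnorm(n_years, 900, 180), 550), 1300)
    spring <- pmin(pmax(stats::rnorm(n_years, 400, 90), 150),
                   pmin(700, annual))
    silking <- pmin(pmax(stats::rnorm(n_years, 110, 45), 0), annual - spring)
    data.frame(year = seq(start_year, length.out = n_years),
               annual_precip = annual, spring_precip = spring,
               silking_precip = silking)
  })
}

#' Atmospheric N deposition from precipitation
#'
#' Linear in precipitation (`coeff` kg N/ha per mm), so summing daily
#' depositions equals applying the coefficient to the annual total. At
#' 0.01 kg N/ha per mm a 700 mm season deposits 7 kg N/ha.
#'
#' @param precip_mm daily or annual precipitation, mm (vectorized).
#' @param coeff deposition coefficient, kg N/ha per mm.
#' @return deposited N, kg N/ha.
#' @export
n_deposition <- function(precip_mm, coeff = 0.01) {
  if (any(precip_mm < 0)) stop("precipitation must be >= 0")
  coeff * precip_mm
}

#' Fertilizer N loss fraction from spring precipitation
#'
#' Exponential loss of fertilizer N (denitrification plus leaching) with
#' spring precipitation:
#' `min(loss_cap, loss_base * exp(loss_exp_rate * (P - precip_ref)))`.
#' At the reference precipitation the fraction equals `loss_base`.
#'
#' @param spring_precip spring window precipitation, mm (vectorized).
#' @param params a [generator_params()].
#' @return fraction of applied fertilizer N lost, in [0, loss_cap].
#' @export
loss_fraction <- function(spring_precip, params = generator_params()) {
  stopifnot(all(spring_precip >= 0))
  pmin(params$loss_cap,
       params$loss_base *
         exp(params$loss_exp_rate * (spring_precip - params$precip_ref)))
}

#' Soil N supply from mineralization
#'
#' Rotation-dependent plant-available soil N, declining linearly with spring
#' precipitation above the reference (floored at half the base supply):
#' `s0_cc * rotation_factor * max(0.5, 1 + slope * (P - precip_ref))`.
#' The soybean-corn rotation carries `sc_supply_factor` (default 1.5, i.e.
#' 50% more supply than continuous corn — the rotation credit).
#'
#' @param spring_precip spring window precipitation, mm (vectorized).
#' @param rotation `"CC"`, `"SC"` or `"SC_val"` (SC_val uses the SC factor).
#' @param params a [generator_params()].
#' @return soil N supply, kg N/ha (excluding deposition; see
#'   [generate_experiment()] which folds deposition in).
#' @export
n_supply <- function(spring_precip, rotation, params = generator_params()) {
  stopifnot(all(spring_precip >= 0))
  fac <- ifelse(rotation == "CC", 1, params$sc_supply_factor)
  params$s0_cc * fac *
    pmax(0.5, 1 + params$supply_precip_slope *
           (spring_precip - params$precip_ref))
}

# Plateau-clamped quadratic in available N; vertex A0 = -b_av / (2 c_av).
qp_available <- function(A, params) {
  A0 <- -params$b_av / (2 * params$c_av)
  A <- pmin(A, A0)
  pmax(0, params$y0 + params$b_av * A + params$c_av * A^2)
}

#' Expected yield of the generating process
#'
#' Available N is supply plus recovered fertilizer,
#' `A = S + (1 - L) * n_rate`; expected yield is
#' `year_factor * max(0, clampedQP(A))` where clampedQP is the
#' quadratic-plateau in available N with vertex `A0 = -b_av / (2 c_av)`.
#'
#' @param n_rate fertilizer N, kg N/ha (vectorized).
#' @param supply soil N supply (deposition included), kg N/ha.
#' @param loss fertilizer loss fraction in [0, 1].
#' @param year_factor multiplicative year effect.
#' @param params a [generator_params()].
#' @return expected yield, kg/ha.
#' @export
true_yield <- function(n_rate, supply, loss, year_factor = 1,
                       params = generator_params()) {
  A <- supply + (1 - loss) * n_rate
  year_factor * qp_available(A, params)
}

#' Closed-form true economic optimum of the generating process
#'
#' Profit per hectare (in grain mass) is `yield(N) - ratio * N`. Setting the
#' derivative to zero on the quadratic arm:
#' `year_factor * (b_av + 2 c_av A) * (1 - L) = ratio`, so
#' `A* = (ratio / ((1 - L) * year_factor) - b_av) / (2 c_av)` and
#' `N* = (A* - S) / (1 - L)`, clamped below at zero (saturated supply).
#' The yield at the optimum follows from [true_yield()]. An internal dense
#' numeric maximization cross-checks the closed form; a discrepancy beyond
#' 0.5 kg N raises an error (it would indicate a broken parameterization).
#'
#' @inheritParams true_yield
#' @param price_ratio break-even kg grain per kg N.
#' @return list `eonr`, `yeonr`, `boundary` (`"interior"` or `"at_zero"`).
#' @export
true_optimum <- function(supply, loss, year_factor = 1,
                         params = generator_params(),
                         price_ratio = params$price_ratio) {
  stopifnot(loss < 1, params$c_av < 0)
  A_star <- (price_ratio / ((1 - loss) * year_factor) - params$b_av) /
    (2 * params$c_av)
  n_star <- (A_star - supply) / (1 - loss)
  boundary <- "interior"
  if (n_star <= 0) { n_star <- 0; boundary <- "at_zero" }
  # internal consistency check against dense profit maximization
  grid <- seq(0, max(600, 2 * n_star), by = 0.05)
  prof <- true_yield(grid, supply, loss, year_factor, params) -
    price_ratio * grid
  n_num <- grid[which.max(prof)]
  if (abs(n_num - n_star) > 0.5)
    stop("closed-form optimum disagrees with numeric maximization")
  list(eonr = n_star,
       yeonr = true_yield(n_star, supply, loss, year_factor, params),
       boundary = boundary)
}

#' Generate a complete synthetic multi-year N-rate experiment
#'
#' Draws weather, year effects, supply and loss per year and rotation, and
#' replicate-level corn yields at the trial's N rates; soybean-corn plots
#' also carry soybean rows whose yields are independent of the N applied to
#' the prior corn (no carryover, by construction). Deposition
#' (`deposition_coeff * annual_precip`) is folded into the supply term.
#' The returned truth table holds, per year and rotation, the realized
#' supply, loss fraction, year factor and closed-form true optimum — the
#' ground truth that recovery tests compare estimates against.
#'
#' @param n_years number of trial years (>= 2).
#' @param params a [generator_params()].
#' @param seed optional integer seed; one seeded stream drives all draws.
#' @param start_year first calendar year label.
#' @return object of class `synthetic_experiment`: list with `trial` (a
#'   `trial_table` of corn and soybean rows), `weather` (see
#'   [simulate_weather()]), `truth` (data.frame `year`, `rotation`,
#'   `supply`, `loss`, `year_factor`, `true_eonr`, `true_yeonr`,
#'   `boundary`), and `params`.
#' @export
generate_experiment <- function(n_years, params = generator_params(),
                                seed = NULL, start_year = 2001L) {
  stopifnot(n_years >= 2)
  with_seed(seed, {
    weather <- simulate_weather(n_years, params, seed = NULL,
                                start_year = start_year)
    rates <- params$n_rates
    reps <- seq_len(params$n_reps)
    trial_rows <- list()
    truth_rows <- list()
    for (i in seq_len(n_years)) {
      yr <- weather$year[i]
      sp <- weather$spring_precip[i]
      yf <- stats::rnorm(1, 1, params$year_effect_cv)
      while (yf < 0.4) yf <- stats::rnorm(1, 1, params$year_effect_cv)
      dep <- n_deposition(weather$annual_precip[i], params$deposition_coeff)
      L <- loss_fraction(sp, params)
      for (rot in c("CC", "SC")) {
        S <- n_supply(sp, rot, params) + dep
        mu <- true_yield(rates, S, L, yf, params)
        for (r in reps) {
          noise <- 1 + stats::rnorm(length(rates), 0, params$rep_cv)
          trial_rows[[length(trial_rows) + 1L]] <- data.frame(
            year = yr, rotation = rot, crop = "corn", n_rate = rates,
            rep = r, yield = pmax(0, mu * noise))
        }
        opt <- true_optimum(S, L, yf, params)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          year = yr, rotation = rot, supply = S, loss = L, year_factor = yf,
          true_eonr = opt$eonr, true_yeonr = opt$yeonr,
          boundary = opt$boundary, stringsAsFactors = FALSE)
      }
      # soybean phase of the SC rotation: independent of prior corn N
      for (r in reps) {
        soy <- pmax(0, stats::rnorm(length(rates), params$soy_mean,
                                    params$soy_sd))
        trial_rows[[length(trial_rows) + 1L]] <- data.frame(
          year = yr, rotation = "SC", crop = "soybean", n_rate = rates,
          rep = r, yield = soy)
      }
    }
    trial <- do.call(rbind, trial_rows)
    class(trial) <- c("trial_table", "data.frame")
    structure(list(trial = trial, weather = weather,
                   truth = do.call(rbind, truth_rows), params = params),
              class = "synthetic_experiment")
  })
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf("Synthetic N-rate experiment: %d years x %d rotations, %d rates x %d reps (%d rows)\n",
              nrow(x$weather), length(unique(x$truth$rotation)),
              length(x$params$n_rates), x$params$n_reps, nrow(x$trial)))
  cat(sprintf("  true EONR range: %.0f-%.0f kg N/ha\n",
              min(x$truth$true_eonr), max(x$truth$true_eonr)))
  invisible(x)
}

#' Estimate yearly optima from an experiment via the fitting chain
#'
#' Runs fit-select-optimize per year and rotation on a trial table and
#' returns one row per group with the estimated EONR/YEONR alongside any
#' available truth. Years whose response is non-significant or non-converged
#' come back with `NA` optima (undefined, never zero).
#'
#' @param trial a `trial_table` (corn rows are used).
#' @param econ an [econ_config()].
#' @param alpha model-selection significance level.
#' @param level `"replicate"` or `"mean"` fitting (treatment means).
#' @return data.frame `year`, `rotation`, `eonr`, `yeonr`, `boundary`, `form`.
#' @export
estimate_yearly_optima <- function(trial, econ = econ_config(), alpha = 0.05,
                                   level = c("replicate", "mean")) {
  level <- match.arg(level)
  corn <- trial[trial$crop == "corn", , drop = FALSE]
  out <- list()
  for (grp in split(corn, list(corn$year, corn$rotation), drop = TRUE)) {
    x <- grp$n_rate; y <- grp$yield
    if (level == "mean") {
      ag <- stats::aggregate(y, by = list(x = x), FUN = mean)
      x <- ag$x; y <- ag[[2L]]
    }
    fit <- tryCatch(fit_group(x, y, alpha = alpha, level = level),
                    error = function(e) NULL)
    est <- eonr(fit, econ, max_rate = max(grp$n_rate),
                year = grp$year[1], rotation = grp$rotation[1])
    out[[length(out) + 1L]] <- data.frame(
      year = grp$year[1], rotation = grp$rotation[1],
      eonr = est$eonr, yeonr = est$yeonr, boundary = est$boundary,
      form = if (is.null(fit)) NA_character_ else fit$form,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res[order(res$year, res$rotation), , drop = FALSE]
}
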