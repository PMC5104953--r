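#' Construct an optimum N rate estimate
#'
#' Container for an economic optimum N rate (EONR) and the yield at the
#' optimum (YEONR), with a boundary flag recording whether the estimate is
#' interior, censored at zero or at the maximum tested rate, or undefined
#' (no significant / concave response).
#'
#' @param eonr economic optimum N rate, kg N/ha (`NA` when undefined).
#' @param yeonr yield at the optimum, kg/ha (`NA` when undefined).
#' @param method `"regression_eonr"` or `"rtn"`.
#' @param year calendar year, or `NA` for a site-level estimate.
#' @param rotation rotation label, or `NA`.
#' @param boundary one of `"interior"`, `"at_zero"`, `"at_max"`, `"undefined"`.
#' @return object of class `optimum_estimate`.
#' @export
optimum_estimate <- function(eonr, yeonr = NA_real_,
                             method = c("regression_eonr", "rtn"),
                             year = NA, rotation = NA,
                             boundary = c("interior", "at_zero", "at_max",
                                          "undefined")) {
  method <- match.arg(method)
  boundary <- match.arg(boundary)
  if (boundary == "undefined") { eonr <- NA_real_; yeonr <- NA_real_ }
  stopifnot(is.na(eonr) || eonr >= 0)
  structure(list(eonr = as.numeric(eonr), yeonr = as.numeric(yeonr),
                 method = method, year = year, rotation = rotation,
                 boundary = boundary),
            class = "optimum_estimate")
}

#' @export
print.optimum_estimate <- function(x, ...) {
  if (x$boundary == "undefined") {
    cat("Optimum N rate: undefined (no usable response)\n")
  } else {
    cat(sprintf("Optimum N rate (%s): EONR = %.1f kg N/ha, YEONR = %.0f kg/ha [%s]\n",
                x$method, x$eonr, x$yeonr, x$boundary))
  }
  invisible(x)
}

#' Economic optimum N rate from a fitted response curve
#'
#' Sets the first derivative of the fitted yield response equal to the
#' fertilizer:grain price ratio and solves for N. For the quadratic,
#' \eqn{N^* = (r - b) / (2c)} with price ratio \eqn{r}; for the
#' quadratic-plateau the solution is additionally capped at the join point
#' (beyond it the slope is zero, below any positive price ratio). The result
#' is clamped to `[0, max_rate]` with the boundary flag set accordingly.
#' A non-converged fit or non-negative curvature (no interior profit maximum)
#' gives an undefined estimate, never an error.
#'
#' @param fit a `response_fit`.
#' @param econ an [econ_config()].
#' @param max_rate largest admissible N rate, kg N/ha; defaults to the
#'   largest rate in the fitted data (estimates are censored, not
#'   extrapolated, beyond the tested range).
#' @param year,rotation labels carried into the result.
#' @return an [optimum_estimate()] with `method = "regression_eonr"`.
#' @export
#' @examples
#' d <- data.frame(n = rep(c(0, 67, 134, 201, 268), 4))
#' d$y <- 4000 + 50 * d$n - 0.09 * d$n^2
#' eonr(fit_quadratic(d$n, d$y))  # (5.6 - 50) / (2 * -0.09) = 246.7
eonr <- function(fit, econ = econ_config(), max_rate = NULL,
                 year = NA, rotation = NA) {
  if (is.null(fit) || !isTRUE(fit$converged) || !is.finite(fit$c) || fit$c >= 0)
    return(optimum_estimate(NA, method = "regression_eonr", year = year,
                            rotation = rotation, boundary = "undefined"))
  if (is.null(max_rate)) max_rate <- max(fit$x)
  r <- econ$price_ratio
  n_star <- (r - fit$b) / (2 * fit$c)
  if (fit$form == "quadratic_plateau") n_star <- min(n_star, fit$x0)
  boundary <- "interior"
  if (n_star <= 0) { n_star <- 0; boundary <- "at_zero" }
  if (n_star >= max_rate) { n_star <- max_rate; boundary <- "at_max" }
  optimum_estimate(n_star, predict(fit, n_rate = n_star),
                   method = "regression_eonr", year = year,
                   rotation = rotation, boundary = boundary)
}

#' Optimum N rate by the return-to-N scan
#'
#' Profit-based optimum over a fine fertilizer grid, the fitted-curve-free
#' analogue of the regression EONR: given yields at every grid rate, the
#' marginal net return between consecutive rates is
#' \eqn{\Delta R_i = (Y_{i+1} - Y_i) - r (N_{i+1} - N_i)} in grain-mass
#' units, and the optimum is where it first reaches zero. Two readings are
#' computed: the first zero-crossing of the marginal return, and the grid
#' maximizer of cumulative return \eqn{Y(N) - rN}. For concave curves they
#' coincide; when they disagree (noisy, non-concave yields) the cumulative
#' maximizer is returned and the discrepancy is recorded in the
#' `discrepancy` attribute.
#'
#' @param n_rate sorted, uniformly spaced grid of N rates (kg N/ha),
#'   default every 5 kg from 0 to 350.
#' @param yield yields at each grid rate (kg/ha).
#' @param econ an [econ_config()].
#' @param year,rotation labels carried into the result.
#' @return an [optimum_estimate()] with `method = "rtn"`; attribute
#'   `discrepancy` is the signed grid difference (kg N/ha) between the two
#'   readings.
#' @export
rtn_optimum <- function(n_rate, yield, econ = econ_config(),
                        year = NA, rotation = NA) {
  if (length(n_rate) != length(yield) || length(n_rate) < 2)
    stop("n_rate and yield must be equal-length vectors of length >= 2")
  if (is.unsorted(n_rate, strictly = TRUE))
    stop("n_rate grid must be strictly increasing")
  steps <- diff(n_rate)
  if (max(steps) - min(steps) > 1e-8 * max(steps))
    stop("n_rate grid must be uniformly spaced (gapped grid)")
  r <- econ$price_ratio

  cum_ret <- yield - r * n_rate
  i_max <- which.max(cum_ret)            # first index on ties -> least N
  marg <- diff(yield) - r * steps
  first_neg <- which(marg < 0)
  i_cross <- if (length(first_neg)) first_neg[1] else length(n_rate)

  opt <- n_rate[i_max]
  boundary <- if (opt <= n_rate[1]) "at_zero"
              else if (i_max == length(n_rate)) "at_max" else "interior"
  est <- optimum_estimate(opt, yield[i_max], method = "rtn", year = year,
                          rotation = rotation, boundary = boundary)
  attr(est, "discrepancy") <- n_rate[i_cross] - opt
  est
}

#' Site mean optimum N rate
#'
#' Pools a multi-year trial into a single site-level optimum two ways.
#' `"across_years"` averages the defined yearly EONR/YEONR estimates and
#' reports their standard deviation; undefined (non-responsive) years are
#' excluded, never treated as zero, and the count of usable years is
#' reported. `"pooled"` first averages corn yields per N rate across years,
#' then runs the full fit-select-optimize chain once on the mean response
#' (the approach used for regional N recommendations); it has no SD.
#'
#' @param x for `"across_years"`, a list of yearly [optimum_estimate()]s;
#'   for `"pooled"`, a `trial_table` (or data.frame with `year`, `n_rate`,
#'   `yield`, optionally restricted to one rotation) spanning >= 2 years.
#' @param method `"across_years"` or `"pooled"`.
#' @param econ an [econ_config()] (pooled only).
#' @param alpha model-selection significance level (pooled only).
#' @param technique pooled chain: `"regression"` (fit then derivative) or
#'   `"rtn"` (predicts the selected fit on the scan grid, then scans).
#' @param cfg an [analysis_config()] supplying the RTN grid.
#' @return object of class `site_mean`: list with `method`, `mean_eonr`,
#'   `sd_eonr` (`NA` for pooled), `mean_yeonr`, `n_years`, `boundary`.
#' @export
site_mean <- function(x, method = c("across_years", "pooled"),
                      econ = econ_config(), alpha = 0.05,
                      technique = c("regression", "rtn"),
                      cfg = analysis_config()) {
  method <- match.arg(method)
  technique <- match.arg(technique)

  if (method == "across_years") {
    stopifnot(is.list(x))
    ests <- Filter(function(e) inherits(e, "optimum_estimate") &&
                     e$boundary != "undefined" && is.finite(e$eonr), x)
    if (length(ests) < 2)
      return(structure(list(method = method, mean_eonr = NA_real_,
                            sd_eonr = NA_real_, mean_yeonr = NA_real_,
                            n_years = length(ests), boundary = "undefined"),
                       class = "site_mean"))
    e <- vapply(ests, `[[`, numeric(1), "eonr")
    yv <- vapply(ests, `[[`, numeric(1), "yeonr")
    return(structure(list(method = method, mean_eonr = mean(e),
                          sd_eonr = stats::sd(e), mean_yeonr = mean(yv),
                          n_years = length(ests), boundary = "interior"),
                     class = "site_mean"))
  }

  # pooled: mean yield per rate across years, then one optimization chain
  df <- as.data.frame(x)
  if ("crop" %in% names(df)) df <- df[df$crop == "corn", , drop = FALSE]
  stopifnot(all(c("year", "n_rate", "yield") %in% names(df)))
  if (length(unique(df$year)) < 2) stop("pooled site mean needs >= 2 years")
  pooled <- stats::aggregate(yield ~ n_rate, data = df, FUN = mean)
  pooled <- pooled[order(pooled$n_rate), ]

  fit <- fit_group(pooled$n_rate, pooled$yield, alpha = alpha, level = "mean")
  est <- if (is.null(fit)) {
    optimum_estimate(NA, method = if (technique == "rtn") "rtn" else
      "regression_eonr", boundary = "undefined")
  } else if (technique == "regression") {
    eonr(fit, econ, max_rate = max(pooled$n_rate))
  } else {
    g <- cfg$rtn_grid
    grid <- seq(g[1], g[2], by = g[3])
    grid <- grid[grid <= max(pooled$n_rate)]  # censor at tested range
    rtn_optimum(grid, predict(fit, n_rate = grid), econ)
  }
  structure(list(method = method, mean_eonr = est$eonr, sd_eonr = NA_real_,
                 mean_yeonr = est$yeonr, n_years = length(unique(df$year)),
                 boundary = est$boundary),
            class = "site_mean")
}

#' @export
print.site_mean <- function(x, ...) {
  if (x$boundary == "undefined") {
    cat(sprintf("Site mean optimum (%s): undefined (%d usable years)\n",
                x$method, x$n_years))
  } else if (x$method == "across_years") {
    cat(sprintf("Site mean optimum (across years, n = %d): EONR %.0f +/- %.0f kg N/ha, YEONR %.0f kg/ha\n",
                x$n_years, x$mean_eonr, x$sd_eonr, x$mean_yeonr))
  } else {
    cat(sprintf("Site mean optimum (pooled, %d years): EONR %.0f kg N/ha, YEONR %.0f kg/ha [%s]\n",
                x$n_years, x$mean_eonr, x$mean_yeonr, x$boundary))
  }
  invisible(x)
}

#' Signed difference between two optimum estimates
#'
#' Reference minus candidate EONR, in kg N/ha — the comparison reported when
#' contrasting observed against simulated site means or one derivation
#' technique against another. Operands may be [optimum_estimate()]s or
#' [site_mean()] results; both must be defined.
#'
#' @param reference,candidate `optimum_estimate` or `site_mean` objects.
#' @return signed difference in kg N/ha (exact, not rounded), or `NA` when
#'   either operand is undefined.
#' @export
method_difference <- function(reference, candidate) {
  get_eonr <- function(z) {
    if (inherits(z, "optimum_estimate")) {
      if (z$boundary == "undefined") NA_real_ else z$eonr
    } else if (inherits(z, "site_mean")) {
      if (z$boundary == "undefined") NA_real_ else z$mean_eonr
    } else stop("operands must be optimum_estimate or site_mean objects")
  }
  a <- get_eonr(reference); b <- get_eonr(candidate)
  if (is.na(a) || is.na(b)) return(NA_real_)
  a - b
}
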