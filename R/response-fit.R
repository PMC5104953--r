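#' Fit a yield response curve to nitrogen rate
#'
#' The workhorse of the package: fits grain yield against fertilizer N rate
#' with either a quadratic
#' \deqn{y = a + b x + c x^2}
#' or a smooth quadratic-plus-plateau
#' \deqn{y = a + b x + c x^2 \ (x < x_0), \quad y = a + b x_0 + c x_0^2 \ (x \ge x_0)}
#' where the join point is tied to the curvature by \eqn{x_0 = -b/(2c)}
#' (continuous first derivative), so the slope entering the economic-optimum
#' calculation is well defined everywhere.
#'
#' The quadratic is ordinary least squares. The quadratic-plateau is fitted by
#' profiling the join point over a deterministic dense grid spanning
#' `[min(x), 1.5 * max(x)]` — for a fixed join point the model is linear in
#' its remaining parameters — followed by local refinement of the best
#' bracket with [stats::optimize()]. No random initialization is used, so
#' results are seed-independent. A plateau fit is reported as non-converged
#' (`converged = FALSE`), never as an error, when the best solution has
#' non-negative curvature or a join point pinned at the profile boundary.
#'
#' @param formula a formula `yield ~ n_rate` naming columns of `data`.
#' @param data a data.frame (e.g. a `trial_table` subset for one year and
#'   rotation) or any data.frame with the two variables.
#' @param form `"quadratic"` or `"quadratic_plateau"`.
#' @param level `"replicate"` to fit all rows as given (default), `"mean"`
#'   to average yields per N rate first.
#' @param x0_grid_n number of profile grid points for the plateau fit.
#' @return An object of class `response_fit`: a list with elements `form`,
#'   `a`, `b`, `c` (coefficients; kg/ha, kg grain per kg N, kg grain per
#'   (kg N)^2), `x0` (join point, kg N/ha; `NA` for the quadratic),
#'   `ss_res`, `r2`, `p_value` (overall F-test against the intercept-only
#'   model), `converged`, `n_obs`, `fit_level`, and the fitted `x`/`y` data.
#' @seealso [select_response()], [eonr()], [predict.response_fit()]
#' @export
#' @examples
#' d <- data.frame(n_rate = rep(c(0, 67, 134, 201, 268), each = 4))
#' d$yield <- 4000 + 50 * d$n_rate - 0.09 * d$n_rate^2
#' fit <- response_fit(yield ~ n_rate, d)
#' coef(fit)
#' predict(fit, n_rate = c(0, 150))
response_fit <- function(formula, data,
                         form = c("quadratic", "quadratic_plateau"),
                         level = c("replicate", "mean"),
                         x0_grid_n = 300L) {
  form <- match.arg(form)
  level <- match.arg(level)
  mf <- stats::model.frame(formula, data)
  y <- as.numeric(mf[[1L]])
  x <- as.numeric(mf[[2L]])
  if (level == "mean") {
    ag <- stats::aggregate(y, by = list(x = x), FUN = mean)
    x <- ag$x
    y <- ag[[2L]]
  }
  fit_response_xy(x, y, form = form, level = level, x0_grid_n = x0_grid_n)
}

# Internal engine on bare vectors; exported wrappers feed it.
fit_response_xy <- function(x, y, form, level = "replicate", x0_grid_n = 300L) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(y)
  n_rates <- length(unique(x))
  if (n_rates < 3)
    stop("unfittable group: need >= 3 distinct N rates, got ", n_rates)
  if (n < 4) stop("unfittable group: need >= 4 observations, got ", n)

  ss_tot <- sum((y - mean(y))^2)

  if (form == "quadratic") {
    fit <- stats::lm(y ~ x + I(x^2))
    cf <- stats::coef(fit)
    ss_res <- sum(stats::resid(fit)^2)
    out <- list(form = "quadratic",
                a = unname(cf[1]), b = unname(cf[2]), c = unname(cf[3]),
                x0 = NA_real_, ss_res = ss_res,
                r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 0,
                p_value = overall_f_p(ss_tot, ss_res, n, p = 3L),
                converged = TRUE, n_obs = n, fit_level = level,
                x = x, y = y)
    return(structure(out, class = "response_fit"))
  }

  # quadratic-plateau: profile x0; for fixed x0 the model is linear in (a, c)
  # via basis z(x) = x^2 - 2*x0*x (x <= x0), -x0^2 (x > x0); b = -2*c*x0.
  lo <- max(min(x), 1e-8)
  hi <- 1.5 * max(x)
  grid <- seq(lo, hi, length.out = x0_grid_n)
  prof <- vapply(grid, qp_profile_ss, numeric(1), x = x, y = y)
  k <- which.min(prof)
  bracket <- c(grid[max(1L, k - 1L)], grid[min(length(grid), k + 1L)])
  opt <- stats::optimize(qp_profile_ss, interval = bracket, x = x, y = y,
                         tol = 1e-6)
  x0 <- opt$minimum
  par <- qp_profile_fit(x0, x, y)
  ss_res <- par$ss
  boundary_tol <- (hi - lo) / (x0_grid_n - 1)
  converged <- is.finite(ss_res) && par$c < 0 &&
    x0 > lo + boundary_tol && x0 < hi - boundary_tol
  out <- list(form = "quadratic_plateau",
              a = par$a, b = par$b, c = par$c, x0 = x0,
              ss_res = ss_res,
              r2 = if (ss_tot > 0) max(0, 1 - ss_res / ss_tot) else 0,
              p_value = overall_f_p(ss_tot, ss_res, n, p = 3L),
              converged = converged, n_obs = n, fit_level = level,
              x = x, y = y)
  structure(out, class = "response_fit")
}

# OLS of y on the plateau basis for a fixed join point; returns a, b, c, ss.
# Two-parameter regression solved in closed form (called ~300x per fit).
qp_profile_fit <- function(x0, x, y) {
  z <- ifelse(x <= x0, x^2 - 2 * x0 * x, -x0^2)
  zc <- z - mean(z)
  szz <- sum(zc^2)
  if (szz == 0) return(list(a = NA, b = NA, c = NA, ss = Inf))
  chat <- sum(zc * (y - mean(y))) / szz
  ahat <- mean(y) - chat * mean(z)
  res <- y - ahat - chat * z
  list(a = ahat, b = -2 * chat * x0, c = chat, ss = sum(res^2))
}

qp_profile_ss <- function(x0, x, y) qp_profile_fit(x0, x, y)$ss

# Overall model F-test against the intercept-only model, p parameters total.
overall_f_p <- function(ss_tot, ss_res, n, p) {
  if (ss_tot <= 0 || n <= p) return(1)
  f <- ((ss_tot - ss_res) / (p - 1)) / (ss_res / (n - p))
  if (!is.finite(f)) return(if (ss_res < ss_tot) 0 else 1)
  stats::pf(f, p - 1, n - p, lower.tail = FALSE)
}

#' Fit a quadratic yield response
#'
#' Convenience wrapper around [response_fit()] on bare vectors.
#'
#' @param x N rates (kg N/ha).
#' @param y yields (kg/ha).
#' @param level recorded fit level label.
#' @return a `response_fit` of form `"quadratic"`.
#' @export
fit_quadratic <- function(x, y, level = "replicate")
  fit_response_xy(x, y, form = "quadratic", level = level)

#' Fit a quadratic-plus-plateau yield response
#'
#' Convenience wrapper around [response_fit()] on bare vectors; see that
#' help page for the join-point parameterization and profiling strategy.
#'
#' @inheritParams fit_quadratic
#' @param x0_grid_n profile grid resolution.
#' @return a `response_fit` of form `"quadratic_plateau"`.
#' @export
fit_quadratic_plateau <- function(x, y, level = "replicate", x0_grid_n = 300L)
  fit_response_xy(x, y, form = "quadratic_plateau", level = level,
                  x0_grid_n = x0_grid_n)

#' Select between candidate response fits
#'
#' Model selection rule for one year-by-rotation group: drop candidates that
#' did not converge or whose overall regression is not significant at
#' `alpha`; among survivors keep the one with the smaller residual sum of
#' squares (equivalently the larger R^2 on the same data). Exact ties go to
#' the quadratic-plateau, the biologically bounded form. Returns `NULL` when
#' nothing survives — a non-responsive (or unfittable) group whose optimum is
#' left undefined.
#'
#' @param fq quadratic `response_fit`.
#' @param fqp quadratic-plateau `response_fit`.
#' @param alpha significance level (default 0.05).
#' @return the selected `response_fit` with an added `selection` attribute
#'   (`"smaller_ss"`, `"only_survivor"`, or `"tie_prefers_plateau"`), or
#'   `NULL`.
#' @export
select_response <- function(fq, fqp, alpha = 0.05) {
  ok <- function(f) !is.null(f) && inherits(f, "response_fit") &&
    isTRUE(f$converged) && is.finite(f$p_value) && f$p_value < alpha
  keep_q <- ok(fq); keep_p <- ok(fqp)
  if (!keep_q && !keep_p) return(NULL)
  if (keep_q && !keep_p) { attr(fq, "selection") <- "only_survivor"; return(fq) }
  if (!keep_q && keep_p) { attr(fqp, "selection") <- "only_survivor"; return(fqp) }
  if (fqp$ss_res < fq$ss_res) { attr(fqp, "selection") <- "smaller_ss"; return(fqp) }
  if (fq$ss_res < fqp$ss_res) { attr(fq, "selection") <- "smaller_ss"; return(fq) }
  attr(fqp, "selection") <- "tie_prefers_plateau"
  fqp
}

#' Fit both response forms to one group and select
#'
#' Runs [fit_quadratic()] and [fit_quadratic_plateau()] on the same
#' observations and applies [select_response()].
#'
#' @inheritParams fit_quadratic
#' @param alpha significance level passed to [select_response()].
#' @return the selected `response_fit`, or `NULL` for a non-responsive group.
#' @export
fit_group <- function(x, y, alpha = 0.05, level = "replicate") {
  fq <- fit_quadratic(x, y, level = level)
  fqp <- fit_quadratic_plateau(x, y, level = level)
  select_response(fq, fqp, alpha = alpha)
}

#' @export
predict.response_fit <- function(object, n_rate = NULL, newdata = NULL, ...) {
  if (is.null(n_rate)) {
    n_rate <- if (is.null(newdata)) object$x else newdata$n_rate
  }
  if (!object$converged) stop("cannot predict from a non-converged fit")
  if (any(n_rate < 0)) stop("n_rate must be >= 0")
  xx <- n_rate
  if (object$form == "quadratic_plateau") xx <- pmin(xx, object$x0)
  object$a + object$b * xx + object$c * xx^2
}

#' @export
fitted.response_fit <- function(object, ...) predict(object, n_rate = object$x)

#' @export
residuals.response_fit <- function(object, ...) object$y - fitted(object)

#' @export
coef.response_fit <- function(object, ...) {
  out <- c(a = object$a, b = object$b, c = object$c)
  if (object$form == "quadratic_plateau") out <- c(out, x0 = object$x0)
  out
}

#' @export
print.response_fit <- function(x, digits = 4, ...) {
  cat("Yield response fit:",
      if (x$form == "quadratic") "quadratic" else "quadratic-plus-plateau", "\n")
  cat("  coefficients:", paste(names(coef(x)),
                               signif(coef(x), digits), sep = " = ",
                               collapse = ", "), "\n")
  cat(sprintf("  n = %d (%s level), R2 = %.3f, p = %.3g, %s\n",
              x$n_obs, x$fit_level, x$r2, x$p_value,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.response_fit <- function(object, price_ratio = 5.6, ...) {
  opt <- if (object$converged) eonr(object, econ_config(price_ratio)) else NULL
  structure(list(fit = object, price_ratio = price_ratio, optimum = opt),
            class = "summary.response_fit")
}

#' @export
print.summary.response_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$optimum) && x$optimum$boundary != "undefined")
    cat(sprintf("  EONR at %.1f:1 price ratio = %.1f kg N/ha (YEONR %.0f kg/ha, %s)\n",
                x$price_ratio, x$optimum$eonr, x$optimum$yeonr,
                x$optimum$boundary))
  else cat("  EONR undefined for this fit\n")
  invisible(x)
}

#' @export
plot.response_fit <- function(x, npoints = 200, ...) {
  graphics::plot(x$x, x$y, xlab = "N rate (kg N/ha)", ylab = "Yield (kg/ha)",
                 pch = 19, ...)
  if (x$converged) {
    xs <- seq(0, max(x$x), length.out = npoints)
    graphics::lines(xs, predict(x, n_rate = xs), col = "red3", lwd = 2)
    if (x$form == "quadratic_plateau" && x$x0 <= max(x$x))
      graphics::abline(v = x$x0, lty = 3)
  }
  invisible(x)
}

#' Simulate replicate yields from a fitted response
#'
#' Draws new yield observations at the fit's N rates from the fitted curve
#' plus Gaussian residual noise with the fit's residual standard deviation
#' (ss_res on n - 3 degrees of freedom).
#'
#' @param object a converged `response_fit`.
#' @param nsim number of simulated response vectors.
#' @param seed optional seed; global RNG state is restored afterwards.
#' @param ... unused.
#' @return data.frame with `n_rate` and `sim_1` ... `sim_nsim` columns.
#' @export
simulate.response_fit <- function(object, nsim = 1, seed = NULL, ...) {
  stopifnot(object$converged)
  sigma <- sqrt(object$ss_res / max(1, object$n_obs - 3))
  mu <- fitted(object)
  with_seed(seed, {
    sims <- replicate(nsim, mu + stats::rnorm(length(mu), 0, sigma))
    out <- data.frame(n_rate = object$x)
    for (j in seq_len(nsim)) out[[paste0("sim_", j)]] <- sims[, j]
    out
  })
}
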