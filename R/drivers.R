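#' Define a within-year precipitation window
#'
#' @param label short window name.
#' @param start,end `"MM-DD"` strings, both endpoints inclusive, with
#'   `start <= end` within one calendar year.
#' @return object of class `window_spec`.
#' @export
#' @examples
#' precip_window("spring", "04-01", "06-30")
precip_window <- function(label, start, end) {
  chk <- function(s) grepl("^[0-1][0-9]-[0-3][0-9]$", s)
  if (!chk(start) || !chk(end)) stop("start/end must be 'MM-DD' strings")
  if (start > end) stop("window start must not be after end")
  structure(list(label = label, start = start, end = end),
            class = "window_spec")
}

#' Default candidate precipitation windows
#'
#' The window set screened when looking for the precipitation interval that
#' best predicts inter-annual EONR variability: spring (Apr-Jun), late
#' spring (May-Jun), June alone, the July silking window (15 days either
#' side of mid-July), and the full calendar year.
#'
#' @return list of [precip_window()]s.
#' @export
default_windows <- function() {
  list(precip_window("apr_jun", "04-01", "06-30"),
       precip_window("may_jun", "05-01", "06-30"),
       precip_window("jun", "06-01", "06-30"),
       precip_window("jul_silking", "07-01", "07-31"),
       precip_window("full_year", "01-01", "12-31"))
}

#' Sum daily precipitation over a window
#'
#' @param daily data.frame for one year with columns `date` (Date or
#'   `"YYYY-MM-DD"`) and `precip` (mm).
#' @param window a [precip_window()].
#' @return window sum in mm, endpoints inclusive.
#' @export
window_sum <- function(daily, window) {
  stopifnot(inherits(window, "window_spec"),
            all(c("date", "precip") %in% names(daily)))
  d <- as.Date(daily$date)
  yr <- format(d[1], "%Y")
  lo <- as.Date(paste0(yr, "-", window$start))
  hi <- as.Date(paste0(yr, "-", window$end))
  if (min(d) > lo || max(d) < hi)
    stop("daily series does not cover window ", window$label)
  sum(daily$precip[d >= lo & d <= hi])
}

#' Simple linear regression with fit statistics
#'
#' Ordinary least squares of `y` on `x` with the slope t-test p-value and
#' R^2 (squared Pearson correlation). Pairs with missing values are dropped.
#'
#' @param x predictor series.
#' @param y response series, same length.
#' @return list of class `regression_result`: `slope`, `intercept`, `r2`,
#'   `p_value`, `n`; all-`NA` statistics with `n` when the predictor has no
#'   variance (flagged via `degenerate = TRUE`).
#' @export
simple_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need >= 3 finite paired points")
  if (stats::var(x) == 0)
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          r2 = NA_real_, p_value = NA_real_, n = n,
                          degenerate = TRUE), class = "regression_result"))
  if (stats::var(y) == 0)  # flat response: exact null line
    return(structure(list(slope = 0, intercept = y[1], r2 = 0, p_value = 1,
                          n = n, degenerate = FALSE),
                     class = "regression_result"))
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = sm$r.squared,
                 p_value = unname(sm$coefficients[2, 4]),
                 n = n, degenerate = FALSE),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Regression degenerate: predictor has zero variance (n =", x$n, ")\n")
  } else {
    cat(sprintf("slope = %.4g, intercept = %.4g, R2 = %.3f, p = %.3g, n = %d\n",
                x$slope, x$intercept, x$r2, x$p_value, x$n))
  }
  invisible(x)
}

#' Screen precipitation windows as EONR predictors
#'
#' Regresses yearly EONR on each candidate window's precipitation sum and
#' ranks the windows by R^2, flagging the significant ones. Years with an
#' undefined EONR are dropped pairwise; the usable count is reported per
#' window.
#'
#' @param daily_by_year data.frame with columns `year`, `date`, `precip`
#'   covering every candidate window in every year.
#' @param eonr_by_year data.frame with columns `year` and `eonr`
#'   (`NA` for undefined years).
#' @param windows list of [precip_window()]s; defaults to
#'   [default_windows()].
#' @param alpha significance flag threshold.
#' @return data.frame ranked by descending R^2: `label`, `slope`,
#'   `intercept`, `r2`, `p_value`, `n`, `significant`.
#' @export
screen_windows <- function(daily_by_year, eonr_by_year,
                           windows = default_windows(), alpha = 0.05) {
  stopifnot(length(windows) > 0,
            all(c("year", "date", "precip") %in% names(daily_by_year)),
            all(c("year", "eonr") %in% names(eonr_by_year)))
  years <- sort(unique(eonr_by_year$year))
  if (length(years) < 3) stop("need >= 3 years")
  rows <- lapply(windows, function(w) {
    sums <- vapply(years, function(yr) {
      window_sum(daily_by_year[daily_by_year$year == yr, , drop = FALSE], w)
    }, numeric(1))
    e <- eonr_by_year$eonr[match(years, eonr_by_year$year)]
    reg <- simple_regression(sums, e)
    data.frame(label = w$label, slope = reg$slope, intercept = reg$intercept,
               r2 = reg$r2, p_value = reg$p_value, n = reg$n,
               significant = isTRUE(reg$p_value < alpha),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$r2, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Soybean N-carryover check
#'
#' Regresses soybean yields on the N rate applied to the prior corn crop.
#' On generator output the slope is null by construction (soybean yields are
#' drawn independently of corn N), so the report documents the absence of a
#' carryover effect; a genuinely fertilized soybean response would surface
#' as a significant positive slope.
#'
#' @param soybean_yield soybean yields, kg/ha.
#' @param prior_corn_n N rate applied to the prior corn crop, kg N/ha,
#'   paired with `soybean_yield`.
#' @return a `regression_result` (see [simple_regression()]).
#' @export
carryover_check <- function(soybean_yield, prior_corn_n)
  simple_regression(prior_corn_n, soybean_yield)

#' Descriptive multi-factor regression of EONR on candidate drivers
#'
#' Ordinary multiple least squares of yearly EONR on any set of numeric
#' predictor columns (precipitation windows, YEONR, application timing...).
#' Reported descriptively only — no variable selection is performed.
#'
#' @param data data.frame with an `eonr` column and the predictors.
#' @param predictors character vector of predictor column names.
#' @return the [stats::lm()] fit.
#' @export
multi_factor_regression <- function(data, predictors) {
  stopifnot("eonr" %in% names(data), all(predictors %in% names(data)))
  fm <- stats::as.formula(paste("eonr ~", paste(predictors, collapse = " + ")))
  stats::lm(fm, data = data)
}

#' Disaggregate seasonal precipitation to a daily series
#'
#' Spreads each year's generated seasonal sums onto calendar days so that
#' window screens can run on generator output: the spring sum over
#' Apr 1 - Jun 30, the silking sum over July, and the remaining annual total
#' over all other days, each with random Exponential(1) daily weights
#' normalized to the window total. Window sums of the result reproduce the
#' seasonal inputs exactly.
#'
#' @param weather output of [simulate_weather()].
#' @param seed optional seed; global RNG state restored.
#' @return data.frame `year`, `date`, `precip` covering every day of every
#'   year.
#' @export
simulate_daily_precip <- function(weather, seed = NULL) {
  with_seed(seed, {
    out <- lapply(seq_len(nrow(weather)), function(i) {
      yr <- weather$year[i]
      days <- seq(as.Date(paste0(yr, "-01-01")),
                  as.Date(paste0(yr, "-12-31")), by = "day")
      md <- format(days, "%m-%d")
      in_spring <- md >= "04-01" & md <= "06-30"
      in_silk <- md >= "07-01" & md <= "07-31"
      other <- !(in_spring | in_silk)
      alloc <- function(idx, total) {
        w <- stats::rexp(sum(idx))
        total * w / sum(w)
      }
      p <- numeric(length(days))
      p[in_spring] <- alloc(in_spring, weather$spring_precip[i])
      p[in_silk] <- alloc(in_silk, weather$silking_precip[i])
      rest <- max(0, weather$annual_precip[i] - weather$spring_precip[i] -
                    weather$silking_precip[i])
      p[other] <- alloc(other, rest)
      data.frame(year = yr, date = days, precip = p)
    })
    do.call(rbind, out)
  })
}
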