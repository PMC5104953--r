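#' Root mean square error
#'
#' \eqn{RMSE = \sqrt{\sum (S_i - O_i)^2 / n}} between paired observed and
#' simulated series, in the input unit.
#'
#' @param observed,simulated equal-length numeric vectors, paired by position.
#' @return RMSE in the input unit.
#' @export
#' @examples
#' rmse(c(10, 12, 14), c(11, 11, 15))  # 1
rmse <- function(observed, simulated) {
  if (length(observed) != length(simulated))
    stop("observed and simulated must have equal length")
  if (!length(observed)) stop("empty series")
  sqrt(mean((simulated - observed)^2))
}

#' Relative root mean square error
#'
#' RMSE expressed as a percentage of the observed mean:
#' \eqn{RRMSE = 100 \cdot RMSE / \bar{O}}. Unit-free, so it is invariant to
#' rescaling both series, and asymmetric in its arguments (the denominator is
#' the observed mean).
#'
#' @inheritParams rmse
#' @return RRMSE in percent; `NA` with a warning when the observed mean is
#'   not positive.
#' @export
rrmse <- function(observed, simulated) {
  o_bar <- mean(observed)
  if (!is.finite(o_bar) || o_bar <= 0) {
    warning("observed mean is not positive; RRMSE undefined")
    return(NA_real_)
  }
  100 * rmse(observed, simulated) / o_bar
}

#' Classify model agreement from relative RMSE
#'
#' Standard crop-model agreement bands: RRMSE of at most `good_max` percent
#' is "good", at least `moderate_max` is "poor", strictly between is
#' "moderate". With the default bands, 15% itself is good and 30% itself is
#' poor.
#'
#' @param rrmse_pct RRMSE in percent (vectorized).
#' @param bands `c(good_max, moderate_max)` in percent.
#' @return factor with levels good, moderate, poor.
#' @export
#' @examples
#' classify_agreement(c(12.3, 19.6, 44.5))  # good, moderate, poor
classify_agreement <- function(rrmse_pct, bands = c(15, 30)) {
  stopifnot(length(bands) == 2L, bands[1] < bands[2])
  out <- ifelse(is.na(rrmse_pct), NA_character_,
                ifelse(rrmse_pct <= bands[1], "good",
                       ifelse(rrmse_pct >= bands[2], "poor", "moderate")))
  factor(out, levels = c("good", "moderate", "poor"))
}

#' Coefficient of variation in percent
#'
#' 100 times the sample (n-1) standard deviation over the mean — the
#' inter-annual variability statistic for yearly yields or optima.
#'
#' @param x numeric vector, length >= 2.
#' @return CV in percent; `NA` with a warning when the mean is not positive.
#' @export
cv_percent <- function(x) {
  if (length(x) < 2) stop("cv_percent needs >= 2 values")
  m <- mean(x)
  if (!is.finite(m) || m <= 0) {
    warning("mean is not positive; CV undefined")
    return(NA_real_)
  }
  100 * stats::sd(x) / m
}

#' Simulated-versus-observed agreement report
#'
#' Pairs a simulated trial against observed treatment means on
#' (year, rotation, n_rate) and reports RMSE, RRMSE and the agreement class
#' per N rate within each rotation, plus a pooled "Mean" row per rotation
#' computed over all of that rotation's pairs (not the average of the
#' per-rate statistics). Simulated values are averaged to one value per
#' treatment when replicated; observed replicates always enter as treatment
#' means.
#'
#' @param obs,sim `trial_table`s (or data.frames with `year`, `rotation`,
#'   `crop`, `n_rate`, `rep`, `yield`); only corn rows are compared.
#' @param bands agreement bands passed to [classify_agreement()].
#' @return data.frame of class `eval_report` with columns `rotation`,
#'   `n_rate` (numeric rate or `"Mean"`), `n`, `obs_mean`, `rmse`, `rrmse`,
#'   `agreement`.
#' @export
evaluation_report <- function(obs, sim, bands = c(15, 30)) {
  om <- treatment_means(as_trial_frame(obs))
  sm <- treatment_means(as_trial_frame(sim))
  m <- merge(om, sm, by = c("year", "rotation", "n_rate"),
             suffixes = c("_obs", "_sim"))
  if (!nrow(m)) stop("no overlapping (year, rotation, n_rate) keys")

  row_for <- function(d, rotation, label) {
    data.frame(rotation = rotation, n_rate = label, n = nrow(d),
               obs_mean = mean(d$yield_obs),
               rmse = rmse(d$yield_obs, d$yield_sim),
               rrmse = rrmse(d$yield_obs, d$yield_sim),
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (rot in unique(m$rotation)) {
    dr <- m[m$rotation == rot, , drop = FALSE]
    for (nr in sort(unique(dr$n_rate)))
      out[[length(out) + 1L]] <-
        row_for(dr[dr$n_rate == nr, , drop = FALSE], rot, as.character(nr))
    out[[length(out) + 1L]] <- row_for(dr, rot, "Mean")
  }
  rep <- do.call(rbind, out)
  rep$agreement <- classify_agreement(rep$rrmse, bands)
  rownames(rep) <- NULL
  class(rep) <- c("eval_report", "data.frame")
  rep
}

# Accept trial_table or a bare data.frame already in canonical units.
as_trial_frame <- function(x) {
  if (inherits(x, "trial_table")) return(x)
  df <- as.data.frame(x)
  if (!"crop" %in% names(df)) df$crop <- "corn"
  if (!"rep" %in% names(df)) df$rep <- 1
  df
}
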