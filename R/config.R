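#' Economic configuration for optimum N rate calculations
#'
#' Bundles the N fertilizer to corn grain price ratio used as the break-even
#' marginal slope. Prices enter as US$ per kg N over US$ per kg grain, so the
#' ratio is a mass-for-mass threshold: at the optimum, one extra kg of
#' fertilizer N must return `price_ratio` kg of grain.
#'
#' @param price_ratio kg grain per kg N at break-even. Default 5.6, the
#'   long-run historical ratio used for US Midwest corn.
#' @return An object of class `econ_config`.
#' @export
#' @examples
#' econ_config()           # default 5.6:1
#' econ_config(price_ratio = 8)
econ_config <- function(price_ratio = 5.6) {
  stopifnot(is.numeric(price_ratio), length(price_ratio) == 1L, price_ratio > 0)
  structure(list(price_ratio = as.numeric(price_ratio)), class = "econ_config")
}

#' Analysis configuration
#'
#' Tuning knobs shared across the pipeline: the return-to-N scan grid, the
#' significance level used for response-model selection, and the relative-RMSE
#' agreement bands.
#'
#' @param rtn_grid numeric `c(start, stop, step)` in kg N/ha for the
#'   return-to-N scan. Default `c(0, 350, 5)`.
#' @param alpha significance level for the overall regression F-test.
#' @param agreement_bands numeric `c(good_max, moderate_max)` in percent
#'   relative RMSE. Default `c(15, 30)`: at most 15% is "good", above 30%
#'   (inclusive) is "poor".
#' @param rng_seed optional integer seed recorded for downstream use.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(rtn_grid = c(0, 350, 5), alpha = 0.05,
                            agreement_bands = c(15, 30), rng_seed = NULL) {
  stopifnot(length(rtn_grid) == 3L, rtn_grid[3] > 0, rtn_grid[2] > rtn_grid[1],
            length(alpha) == 1L, alpha > 0, alpha < 1,
            length(agreement_bands) == 2L,
            agreement_bands[1] > 0, agreement_bands[1] < agreement_bands[2])
  structure(list(rtn_grid = as.numeric(rtn_grid),
                 alpha = as.numeric(alpha),
                 agreement_bands = as.numeric(agreement_bands),
                 rng_seed = rng_seed),
            class = "analysis_config")
}

# Evaluate code with a temporary RNG seed, restoring global RNG state after.
# All stochastic functions route through this so no call leaks global state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
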