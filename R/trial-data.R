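#' Read a nitrogen-rate trial table
#'
#' Reads a plain CSV of replicate-level grain yield observations from an N-rate
#' trial and returns a validated trial table in canonical units (kg/ha for
#' yield, kg N/ha for fertilizer rate). Expected header:
#' `year,rotation,crop,n_rate,rep,yield`.
#'
#' Rotations are `CC` (continuous corn), `SC` (soybean-corn) and `SC_val`
#' (a second soybean-corn entry point, kept distinct but treated identically by
#' all calculations).
#'
#' @param path path to the CSV file.
#' @param units unit of the `yield` column: `"kg_ha"` or `"mg_ha"`
#'   (megagram = metric ton per hectare; multiplied by 1000 internally).
#' @return A `data.frame` of class `trial_table` with columns `year`,
#'   `rotation`, `crop`, `n_rate`, `rep`, `yield` (kg/ha), rows in input order.
#' @seealso [validate_trial()], [write_trial()]
#' @export
read_trial <- function(path, units = c("kg_ha", "mg_ha")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("trial file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_trial_table(raw, units = units)
}

#' Build a trial table from a data frame
#'
#' Validates columns, types and the uniqueness invariant and normalizes yield
#' to kg/ha.
#'
#' @param df data.frame with columns `year`, `rotation`, `crop`, `n_rate`,
#'   `rep`, `yield`.
#' @inheritParams read_trial
#' @return A `trial_table` data.frame (yields in kg/ha).
#' @export
as_trial_table <- function(df, units = c("kg_ha", "mg_ha")) {
  units <- match.arg(units)
  required <- c("year", "rotation", "crop", "n_rate", "rep", "yield")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[required]

  for (col in c("year", "n_rate", "rep", "yield")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("non-numeric ", col, " at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
    if (anyNA(v))
      stop("missing ", col, " at row(s): ",
           paste(utils::head(which(is.na(v)), 5), collapse = ", "))
    df[[col]] <- v
  }
  if (any(df$n_rate < 0))
    stop("negative n_rate at row(s): ",
         paste(utils::head(which(df$n_rate < 0), 5), collapse = ", "))
  if (any(df$yield < 0))
    stop("negative yield at row(s): ",
         paste(utils::head(which(df$yield < 0), 5), collapse = ", "))

  bad_rot <- setdiff(unique(df$rotation), c("CC", "SC", "SC_val"))
  if (length(bad_rot))
    stop("unknown rotation label(s): ", paste(bad_rot, collapse = ", "))
  bad_crop <- setdiff(unique(df$crop), c("corn", "soybean"))
  if (length(bad_crop))
    stop("unknown crop label(s): ", paste(bad_crop, collapse = ", "))

  key <- paste(df$year, df$rotation, df$crop, df$n_rate, df$rep, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (year, rotation, crop, n_rate, rep) key at row(s): ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "))

  if (units == "mg_ha") df$yield <- df$yield * 1000
  rownames(df) <- NULL
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Write a trial table to CSV
#'
#' Inverse of [read_trial()]; yields are converted from the internal kg/ha to
#' the requested unit on the way out, so a write/read round trip is
#' value-identical.
#'
#' @param trial a `trial_table`.
#' @param path output CSV path.
#' @inheritParams read_trial
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path, units = c("kg_ha", "mg_ha")) {
  units <- match.arg(units)
  stopifnot(inherits(trial, "trial_table"))
  out <- as.data.frame(trial)
  if (units == "mg_ha") out$yield <- out$yield / 1000
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a trial table for fitting
#'
#' Report-only screen for problems that make a (year, rotation) corn group
#' unusable or suspicious: fewer than 3 distinct N rates (unfittable),
#' unbalanced replicate counts across rates, and yields beyond a multiple of
#' the group interquartile range from the group median. The data are never
#' modified.
#'
#' @param trial a `trial_table`.
#' @param iqr_mult flag yields outside median +/- `iqr_mult` * IQR of their
#'   (year, rotation, n_rate-pooled) group. Default 3.
#' @return data.frame of findings with columns `year`, `rotation`, `type`
#'   (`unfittable_group`, `unbalanced_reps`, `outlier`) and `detail`;
#'   zero rows when the table is clean.
#' @export
validate_trial <- function(trial, iqr_mult = 3) {
  stopifnot(inherits(trial, "trial_table"), iqr_mult > 0)
  corn <- trial[trial$crop == "corn", , drop = FALSE]
  findings <- list()
  add <- function(year, rotation, type, detail)
    findings[[length(findings) + 1L]] <<- data.frame(
      year = year, rotation = rotation, type = type, detail = detail,
      stringsAsFactors = FALSE)

  for (grp in split(corn, list(corn$year, corn$rotation), drop = TRUE)) {
    yr <- grp$year[1]; rot <- grp$rotation[1]
    n_rates <- sort(unique(grp$n_rate))
    if (length(n_rates) < 3) {
      add(yr, rot, "unfittable_group",
          sprintf("only %d distinct N rate(s)", length(n_rates)))
      next
    }
    reps <- table(grp$n_rate)
    if (length(unique(as.integer(reps))) > 1)
      add(yr, rot, "unbalanced_reps",
          sprintf("replicate counts %s across rates",
                  paste(range(reps), collapse = "-")))
    med <- stats::median(grp$yield)
    iqr <- stats::IQR(grp$yield)
    if (iqr > 0) {
      out <- which(abs(grp$yield - med) > iqr_mult * iqr)
      for (i in out)
        add(yr, rot, "outlier",
            sprintf("yield %.0f kg/ha at N=%g rep %g beyond %.3g x IQR of median",
                    grp$yield[i], grp$n_rate[i], grp$rep[i], iqr_mult))
    }
  }
  if (!length(findings))
    return(data.frame(year = numeric(), rotation = character(),
                      type = character(), detail = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, findings)
  rownames(out) <- NULL
  out
}

# Treatment means of corn yields: one row per year x rotation x n_rate.
treatment_means <- function(trial) {
  corn <- trial[trial$crop == "corn", , drop = FALSE]
  agg <- stats::aggregate(yield ~ year + rotation + n_rate, data = corn, FUN = mean)
  agg[order(agg$year, agg$rotation, agg$n_rate), , drop = FALSE]
}
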