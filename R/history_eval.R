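# Historical operational logs: per-period counts of patients shown for
# review, flagged by the algorithm, and actually contacted. The log CSV
# contract is the exact header "period_start,shown,flagged,contacted" with
# ISO-8601 dates, rows in strictly increasing date order, and
# contacted <= flagged <= shown in every row.

log_header <- c("period_start", "shown", "flagged", "contacted")

validate_log_df <- function(df, where = "log") {
  if (!all(log_header %in% names(df))) {
    stop(where, ": missing required columns ",
         paste(setdiff(log_header, names(df)), collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(df)
  if (n == 0) return(invisible(df))
  # line numbers in messages count the header as line 1
  line <- seq_len(n) + 1L
  bad <- which(is.na(df$period_start))
  if (length(bad)) {
    stop(where, ": malformed date at line ", bad[1] + 1L, call. = FALSE)
  }
  for (col in c("shown", "flagged", "contacted")) {
    bad <- which(is.na(df[[col]]) | df[[col]] < 0)
    if (length(bad)) {
      stop(where, ": malformed ", col, " at line ", line[bad[1]],
           call. = FALSE)
    }
  }
  bad <- which(df$contacted > df$flagged | df$flagged > df$shown)
  if (length(bad)) {
    stop(where, ": count inequality violated (need contacted <= flagged <= ",
         "shown) at line ", line[bad[1]], call. = FALSE)
  }
  if (n > 1 && any(diff(df$period_start) <= 0)) {
    bad <- which(diff(df$period_start) <= 0)[1] + 1L
    stop(where, ": period_start not strictly increasing at line ",
         line[bad], call. = FALSE)
  }
  invisible(df)
}

#' Read a historical operational log
#'
#' @param path Path to a CSV file with header
#'   `period_start,shown,flagged,contacted` and ISO-8601 dates.
#' @return A data.frame of class `rpm_log` with columns `period_start`
#'   (Date) and integer `shown`, `flagged`, `contacted`, validated (dates
#'   strictly increasing, `contacted <= flagged <= shown`). A header-only
#'   file yields zero rows.
#' @export
load_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(period_start = "character"))
  if (!all(log_header %in% names(df))) {
    stop(path, ": expected header ", paste(log_header, collapse = ","),
         call. = FALSE)
  }
  df <- df[, log_header]
  df$period_start <- as.Date(df$period_start, format = "%Y-%m-%d")
  for (col in c("shown", "flagged", "contacted")) {
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  }
  validate_log_df(df, where = path)
  class(df) <- c("rpm_log", "data.frame")
  df
}

#' Write a historical operational log
#'
#' Inverse of [load_log()]: writes the exact CSV contract (unquoted,
#' header `period_start,shown,flagged,contacted`, ISO-8601 dates), so that
#' `load_log(write_log(x, path))` round-trips bit-identically.
#'
#' @param records An `rpm_log` data.frame (see [load_log()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_log <- function(records, path) {
  validate_log_df(records)
  out <- data.frame(
    period_start = format(records$period_start, "%Y-%m-%d"),
    shown = records$shown, flagged = records$flagged,
    contacted = records$contacted
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Unrounded per-period contacted/flagged ratios over periods with
# flagged > 0 (internal; both ratio_statistics and fit_calibration use it).
log_ratios <- function(records) {
  validate_log_df(records)
  keep <- records$flagged > 0
  list(ratios = records$contacted[keep] / records$flagged[keep],
       n_excluded = sum(!keep))
}

#' Contacted-to-flagged ratio statistics of a log
#'
#' Per-period ratio `contacted / flagged`, with mean and sample standard
#' deviation (n-1 denominator) over the periods with at least one flagged
#' patient, reported as percentages to one decimal — the precision at which
#' the study program reported its ratio (mean 51.8%, SD 17.1%). Periods
#' with zero flagged patients have an undefined ratio and are excluded; the
#' excluded count is reported.
#'
#' @param records An `rpm_log` data.frame.
#' @return A list of class `rpm_ratio_stats`: `n_periods` (used),
#'   `mean_ratio` (%), `sd_ratio` (%; `NA` when only one usable period),
#'   `n_excluded`.
#' @export
ratio_statistics <- function(records) {
  lr <- log_ratios(records)
  if (length(lr$ratios) == 0) {
    stop("no periods with flagged > 0; ratio undefined", call. = FALSE)
  }
  structure(
    list(
      n_periods = length(lr$ratios),
      mean_ratio = round(100 * mean(lr$ratios), 1),
      sd_ratio = if (length(lr$ratios) > 1) {
        round(100 * stats::sd(lr$ratios), 1)
      } else NA_real_,
      n_excluded = lr$n_excluded
    ),
    class = "rpm_ratio_stats"
  )
}

#' @export
print.rpm_ratio_stats <- function(x, ...) {
  cat(sprintf(
    "<ratio statistics> contacted/flagged over %d periods: mean %.1f%%, SD %s%% (%d zero-flagged periods excluded)\n",
    x$n_periods, x$mean_ratio,
    if (is.na(x$sd_ratio)) "NA" else sprintf("%.1f", x$sd_ratio),
    x$n_excluded
  ))
  invisible(x)
}

#' Compare model projections with an actual log
#'
#' Projects expected contacts per period from the scenario (demand along the
#' population trajectory) and compares them with the log's actual contacted
#' counts; if a flag probability is supplied, expected flagged counts
#' (`round(f * N) * flag_probability` per cohort) are compared with actual
#' flagged counts as well. Reports per-period absolute and percent errors
#' and the mean absolute percentage error (MAPE) over periods with a
#' positive actual count.
#'
#' @param records An `rpm_log` data.frame.
#' @param scn A [scenario()] describing the program over the log's span;
#'   period 1 of the projection is aligned with the first log row.
#' @param flag_probability Optional probability a shown patient is flagged,
#'   enabling the flagged-count comparison.
#' @return A list of class `rpm_projection_eval`: `comparison` (data.frame
#'   with `period_start`, `actual_contacted`, `projected_contacted`,
#'   `abs_error_contacted`, `pct_error_contacted`, and the flagged
#'   counterparts when available) and `mape` (named vector).
#' @export
projection_vs_actual <- function(records, scn, flag_probability = NULL) {
  validate_log_df(records)
  stopifnot(inherits(scn, "rpm_scenario"))
  n <- nrow(records)
  if (n == 0) stop("empty log", call. = FALSE)
  proj_contact <- numeric(n)
  proj_flag <- if (is.null(flag_probability)) NULL else numeric(n)
  for (j in seq_along(scn$cohorts)) {
    co <- scn$cohorts[[j]]
    tr <- project_population(co, n)
    proj_contact <- proj_contact + co$review_frequency *
      co$contact_fraction * (tr$enrolled + co$new_per_period)
    if (!is.null(proj_flag)) {
      proj_flag <- proj_flag +
        round_half_up(co$review_frequency * tr$enrolled) * flag_probability
    }
  }
  cmp <- data.frame(
    period_start = records$period_start,
    actual_contacted = records$contacted,
    projected_contacted = proj_contact,
    abs_error_contacted = abs(proj_contact - records$contacted),
    pct_error_contacted = ifelse(
      records$contacted > 0,
      100 * abs(proj_contact - records$contacted) / records$contacted,
      NA_real_)
  )
  mape <- c(contacted = mean(cmp$pct_error_contacted, na.rm = TRUE))
  if (!is.null(proj_flag)) {
    cmp$actual_flagged <- records$flagged
    cmp$projected_flagged <- proj_flag
    cmp$abs_error_flagged <- abs(proj_flag - records$flagged)
    cmp$pct_error_flagged <- ifelse(
      records$flagged > 0,
      100 * abs(proj_flag - records$flagged) / records$flagged, NA_real_)
    mape <- c(mape, flagged = mean(cmp$pct_error_flagged, na.rm = TRUE))
  }
  structure(list(comparison = cmp, mape = mape),
            class = "rpm_projection_eval")
}

#' @export
print.rpm_projection_eval <- function(x, ...) {
  cat(sprintf("<projection vs actual> %d periods\n", nrow(x$comparison)))
  for (nm in names(x$mape)) {
    cat(sprintf("  MAPE %s: %.1f%%\n", nm, x$mape[[nm]]))
  }
  invisible(x)
}

#' Fit simulator calibration from a historical log
#'
#' Estimates the simulator's stochastic parameters from an operational log:
#' `contact_ratio_mean` and `contact_ratio_sd` as the (unrounded) mean and
#' sample SD of the per-period contacted/flagged ratio, and
#' `flag_probability` as the mean per-period `flagged / shown` over periods
#' with at least one patient shown. Periods with `shown = 0` are excluded
#' from the flag-probability estimate with a warning; zero-flagged periods
#' are excluded from the ratio statistics.
#'
#' @param records An `rpm_log` data.frame.
#' @return A list of class `rpm_calibration`: `contact_ratio_mean`,
#'   `contact_ratio_sd` (fractions in `[0, 1]`), `flag_probability`,
#'   `n_periods`.
#' @export
fit_calibration <- function(records) {
  lr <- log_ratios(records)
  if (length(lr$ratios) == 0) {
    stop("no periods with flagged > 0; cannot calibrate", call. = FALSE)
  }
  keep <- records$shown > 0
  if (any(!keep)) {
    warning(sum(!keep), " period(s) with shown = 0 excluded from the ",
            "flag-probability estimate", call. = FALSE)
  }
  structure(
    list(
      contact_ratio_mean = mean(lr$ratios),
      contact_ratio_sd = if (length(lr$ratios) > 1) stats::sd(lr$ratios)
        else NA_real_,
      flag_probability = mean(records$flagged[keep] / records$shown[keep]),
      n_periods = nrow(records)
    ),
    class = "rpm_calibration"
  )
}

#' @export
print.rpm_calibration <- function(x, ...) {
  cat(sprintf(
    "<calibration> contact ratio %.3f (SD %.3f), flag probability %.3f, from %d periods\n",
    x$contact_ratio_mean, x$contact_ratio_sd, x$flag_probability,
    x$n_periods
  ))
  invisible(x)
}
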