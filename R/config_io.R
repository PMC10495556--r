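# Scenario configuration files (YAML). The key names are part of the public
# contract:
#   cohorts: list of {name, enrolled, new_per_period, graduation_fraction,
#                     review_frequency, contact_fraction}
#   pool:    {n_providers, hours_per_period, minutes_per_review}
#   period_label: optional

#' Read a scenario configuration file
#'
#' @param path Path to a YAML scenario file (see [write_scenario()] for the
#'   key contract).
#' @return A [scenario()].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$cohorts) || is.null(cfg$pool)) {
    stop(path, ": scenario config needs 'cohorts' and 'pool' keys",
         call. = FALSE)
  }
  cohorts <- lapply(cfg$cohorts, function(co) {
    cohort(
      name = co$name %||% "cohort",
      enrolled = co$enrolled %||% 0,
      new_per_period = co$new_per_period %||% 0,
      graduation_fraction = co$graduation_fraction %||% 0,
      review_frequency = co$review_frequency %||% 1,
      contact_fraction = co$contact_fraction %||% NA_real_
    )
  })
  pool <- provider_pool(
    n_providers = cfg$pool$n_providers,
    hours_per_period = cfg$pool$hours_per_period,
    minutes_per_review = cfg$pool$minutes_per_review,
    reviews_per_hour = cfg$pool$reviews_per_hour
  )
  scenario(cohorts, pool, period_label = cfg$period_label %||% "week",
           demand = cfg$demand)
}

#' Write a scenario configuration file
#'
#' Writes the YAML scenario contract so that
#' `read_scenario(write_scenario(x, path))` round-trips. Unset contact
#' fractions are written as nulls.
#'
#' @param scn A [scenario()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scn, path) {
  stopifnot(inherits(scn, "rpm_scenario"))
  cfg <- list(
    cohorts = lapply(scn$cohorts, function(co) {
      list(
        name = co$name,
        enrolled = co$enrolled,
        new_per_period = co$new_per_period,
        graduation_fraction = co$graduation_fraction,
        review_frequency = co$review_frequency,
        contact_fraction = if (is.na(co$contact_fraction)) NULL else
          co$contact_fraction
      )
    }),
    pool = c(
      list(
        n_providers = scn$pool$n_providers,
        hours_per_period = scn$pool$hours_per_period,
        minutes_per_review = scn$pool$minutes_per_review
      ),
      if (!is.null(scn$pool$reviews_per_hour)) {
        list(reviews_per_hour = scn$pool$reviews_per_hour)
      }
    ),
    period_label = scn$period_label
  )
  if (!is.null(scn$demand)) cfg$demand <- scn$demand
  yaml::write_yaml(cfg, path, precision = 12)
  invisible(path)
}

#' Write a fitted calibration fragment
#'
#' Serialises a [fit_calibration()] result in the configuration format so
#' it can be merged into a simulation config.
#'
#' @param calib An `rpm_calibration` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "rpm_calibration"))
  yaml::write_yaml(list(simulation = list(
    contact_ratio_mean = calib$contact_ratio_mean,
    contact_ratio_sd = calib$contact_ratio_sd,
    flag_probability = calib$flag_probability
  )), path, precision = 12)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
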