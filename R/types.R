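#' Define a monitored patient cohort
#'
#' A cohort is a sub-population of the remote-monitoring program that shares
#' a review cadence and a contact fraction. Demand is computed per cohort and
#' summed, so programs mixing weekly and monthly review (as the study clinic
#' did) are expressed as several cohorts.
#'
#' @param name Cohort label.
#' @param enrolled Currently enrolled patient count \eqn{N \ge 0}.
#' @param new_per_period Expected newly enrolled patients per review period
#'   \eqn{A \ge 0}; may be fractional.
#' @param graduation_fraction Fraction of enrolled patients leaving the
#'   program per period, \eqn{g \in [0, 1]}.
#' @param review_frequency Reviews per patient per period \eqn{f > 0};
#'   1 means every period, 0.25 means every fourth period (monthly cadence
#'   under a weekly period, using the default 4-weeks-per-month convention).
#' @param contact_fraction Fraction of reviewed patients requiring contact,
#'   \eqn{p \in [0, 1]}. May be `NA` to mark a deliberate placeholder (the
#'   study never printed its baseline value); demand computation refuses
#'   placeholders.
#' @return An object of class `rpm_cohort`.
#' @seealso [projected_demand()], [provider_pool()]
#' @examples
#' cohort("weekly", enrolled = 38, new_per_period = 2, contact_fraction = 0.25)
#' @export
cohort <- function(name, enrolled, new_per_period = 0,
                   graduation_fraction = 0, review_frequency = 1,
                   contact_fraction = NA_real_) {
  x <- structure(
    list(
      name = as.character(name)[1],
      enrolled = as.numeric(enrolled)[1],
      new_per_period = as.numeric(new_per_period)[1],
      graduation_fraction = as.numeric(graduation_fraction)[1],
      review_frequency = as.numeric(review_frequency)[1],
      contact_fraction = as.numeric(contact_fraction)[1]
    ),
    class = "rpm_cohort"
  )
  validate_cohort(x)
  x
}

validate_cohort <- function(x) {
  stopifnot(inherits(x, "rpm_cohort"))
  if (is.na(x$enrolled) || x$enrolled < 0) {
    stop("invalid cohort '", x$name, "': enrolled must be >= 0", call. = FALSE)
  }
  if (is.na(x$new_per_period) || x$new_per_period < 0) {
    stop("invalid cohort '", x$name, "': new_per_period must be >= 0",
         call. = FALSE)
  }
  if (is.na(x$graduation_fraction) || x$graduation_fraction < 0 ||
      x$graduation_fraction > 1) {
    stop("invalid cohort '", x$name,
         "': graduation_fraction must be in [0, 1]", call. = FALSE)
  }
  if (is.na(x$review_frequency) || x$review_frequency <= 0) {
    stop("invalid cohort '", x$name, "': review_frequency must be > 0",
         call. = FALSE)
  }
  if (!is.na(x$contact_fraction) &&
      (x$contact_fraction < 0 || x$contact_fraction > 1)) {
    stop("invalid cohort '", x$name, "': contact_fraction must be in [0, 1]",
         call. = FALSE)
  }
  invisible(x)
}

#' @export
print.rpm_cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort '%s'> enrolled=%g new/period=%g graduation=%g f=%g p=%s\n",
    x$name, x$enrolled, x$new_per_period, x$graduation_fraction,
    x$review_frequency,
    if (is.na(x$contact_fraction)) "<unset>" else
      format(x$contact_fraction)
  ))
  invisible(x)
}

#' Define the reviewer workforce
#'
#' The provider pool holds the capacity side of the model: how many providers
#' review flagged patients, how many hours each dedicates per review period,
#' and the average minutes one review (data check plus any message) takes.
#' Review capacity per provider-hour is derived as `60 / minutes_per_review`
#' unless `reviews_per_hour` is supplied directly.
#'
#' @param n_providers Provider headcount \eqn{m \ge 1} (integer).
#' @param hours_per_period Hours each provider allocates per review period
#'   \eqn{h > 0}.
#' @param minutes_per_review Average minutes per patient review \eqn{t > 0}.
#' @param reviews_per_hour Optional direct patients-per-provider-hour figure
#'   overriding the `60 / t` derivation.
#' @return An object of class `rpm_pool`.
#' @examples
#' # the study baseline: 3 CDCESs, 4 h/week, 10 min/review -> 72 reviews/week
#' provider_pool(3, 4, 10)
#' @export
provider_pool <- function(n_providers, hours_per_period, minutes_per_review,
                          reviews_per_hour = NULL) {
  x <- structure(
    list(
      n_providers = as.numeric(n_providers)[1],
      hours_per_period = as.numeric(hours_per_period)[1],
      minutes_per_review = as.numeric(minutes_per_review)[1],
      reviews_per_hour = if (is.null(reviews_per_hour)) NULL else
        as.numeric(reviews_per_hour)[1]
    ),
    class = "rpm_pool"
  )
  validate_pool(x)
  x
}

validate_pool <- function(x) {
  stopifnot(inherits(x, "rpm_pool"))
  m <- x$n_providers
  if (is.na(m) || m < 1 || m != round(m)) {
    stop("invalid pool: n_providers must be a positive integer", call. = FALSE)
  }
  if (is.na(x$hours_per_period) || x$hours_per_period <= 0) {
    stop("invalid pool: hours_per_period must be > 0", call. = FALSE)
  }
  if (is.na(x$minutes_per_review) || x$minutes_per_review <= 0) {
    stop("invalid pool: minutes_per_review must be > 0", call. = FALSE)
  }
  if (!is.null(x$reviews_per_hour) &&
      (is.na(x$reviews_per_hour) || x$reviews_per_hour <= 0)) {
    stop("invalid pool: reviews_per_hour must be > 0", call. = FALSE)
  }
  invisible(x)
}

#' Patients one provider can review per hour
#'
#' @param pool An [provider_pool()] object.
#' @return Reviews per provider-hour (`60 / minutes_per_review`, or the
#'   explicit `reviews_per_hour` override).
#' @export
review_capacity <- function(pool) {
  validate_pool(pool)
  if (!is.null(pool$reviews_per_hour)) pool$reviews_per_hour
  else 60 / pool$minutes_per_review
}

#' @export
print.rpm_pool <- function(x, ...) {
  cat(sprintf(
    "<provider pool> m=%g providers x h=%g hours/period, t=%g min/review (%.3g reviews/provider-hour)\n",
    x$n_providers, x$hours_per_period, x$minutes_per_review,
    review_capacity(x)
  ))
  invisible(x)
}

#' Bundle cohorts and a provider pool into a planning scenario
#'
#' A scenario is the unit the what-if explorer, the simulator and the CLI
#' operate on. Demand is normally computed from the cohorts; alternatively a
#' fixed `demand` may be supplied for scenarios anchored to a known coverage
#' percentage (the study's baseline demand is only recoverable that way, via
#' [demand_from_coverage()], because the baseline contact fraction was never
#' published).
#'
#' @param cohorts A list of [cohort()] objects (or a single cohort).
#' @param pool A [provider_pool()].
#' @param period_label Human-readable period unit, default "week".
#' @param demand Optional fixed demand (contacts per period) overriding the
#'   cohort computation. When set, demand-side what-if axes are unavailable.
#' @return An object of class `rpm_scenario`.
#' @export
scenario <- function(cohorts, pool, period_label = "week", demand = NULL) {
  if (inherits(cohorts, "rpm_cohort")) cohorts <- list(cohorts)
  stopifnot(is.list(cohorts))
  lapply(cohorts, validate_cohort)
  validate_pool(pool)
  if (!is.null(demand)) {
    demand <- as.numeric(demand)[1]
    if (is.na(demand) || demand < 0) {
      stop("invalid scenario: demand must be >= 0", call. = FALSE)
    }
  }
  structure(
    list(cohorts = cohorts, pool = pool,
         period_label = as.character(period_label)[1],
         demand = demand),
    class = "rpm_scenario"
  )
}

#' @export
print.rpm_scenario <- function(x, ...) {
  cat(sprintf("<scenario> %d cohort(s), period = %s\n",
              length(x$cohorts), x$period_label))
  for (co in x$cohorts) print(co)
  print(x$pool)
  d <- tryCatch(projected_demand(x), error = function(e) NA_real_)
  k <- projected_capacity(x$pool)
  if (!is.na(d)) {
    cv <- coverage(d, k)
    cat(sprintf("demand = %.2f contacts/%s, capacity = %.2f reviews/%s, coverage = %d%%\n",
                d, x$period_label, k, x$period_label, cv$reported_coverage))
  } else {
    cat(sprintf("demand = <unset contact fraction>, capacity = %.2f reviews/%s\n",
                k, x$period_label))
  }
  invisible(x)
}
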