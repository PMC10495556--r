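# Core demand / capacity / coverage equations of the planning model.
#
# demand    D = sum_i f_i * p_i * (N_i + A_i)      contacts per period
# capacity  K = (60 / t) * m * h                   reviews per period
# coverage  min(100 * K / D, 100) %                reported to nearest integer
#
# The coverage ratio is capacity over demand, capped at 100% for reporting;
# the raw (uncapped) ratio is retained alongside.

round_half_up <- function(x, digits = 0) {
  # base round() is round-half-even; reporting uses commercial rounding
  p <- 10^digits
  floor(x * p + 0.5) / p
}

as_cohort_list <- function(x) {
  if (inherits(x, "rpm_scenario")) return(x$cohorts)
  if (inherits(x, "rpm_cohort")) return(list(x))
  stopifnot(is.list(x))
  x
}

#' Projected contact demand per period
#'
#' Expected patient contacts per review period, summed over cohorts:
#' \deqn{D = \sum_i f_i \, p_i \, (N_i + A_i)}
#' where \eqn{f} is the review frequency, \eqn{p} the contact fraction,
#' \eqn{N} the enrolled count and \eqn{A} the expected new patients per
#' period. Demand is additive over cohorts and linear in each cohort's
#' population.
#'
#' @param cohorts A list of [cohort()] objects, a single cohort, or a
#'   [scenario()] (whose fixed `demand`, if set, takes precedence).
#' @return Demand in expected contacts per period (fractional).
#' @examples
#' projected_demand(cohort("a", enrolled = 38, new_per_period = 2,
#'                         contact_fraction = 0.25))  # 10
#' @export
projected_demand <- function(cohorts) {
  if (inherits(cohorts, "rpm_scenario") && !is.null(cohorts$demand)) {
    return(cohorts$demand)
  }
  cl <- as_cohort_list(cohorts)
  total <- 0
  for (co in cl) {
    validate_cohort(co)
    if (is.na(co$contact_fraction)) {
      stop("cohort '", co$name, "' has an unset contact_fraction; ",
           "set it before computing demand", call. = FALSE)
    }
    total <- total +
      co$review_frequency * co$contact_fraction *
      (co$enrolled + co$new_per_period)
  }
  total
}

#' Projected review capacity per period
#'
#' Patient reviews the provider pool can deliver per review period:
#' \deqn{K = r \times m \times h}
#' with review capacity \eqn{r = 60 / t} patients per provider-hour,
#' \eqn{m} providers and \eqn{h} hours per provider per period.
#'
#' @param pool A [provider_pool()].
#' @return Reviews deliverable per period.
#' @examples
#' projected_capacity(provider_pool(3, 4, 10))  # 72
#' @export
projected_capacity <- function(pool) {
  validate_pool(pool)
  review_capacity(pool) * pool$n_providers * pool$hours_per_period
}

#' Coverage percentage of demand by capacity
#'
#' Capacity expressed as a percent of demand, capped at 100% for reporting.
#' Zero demand is defined as fully covered (coverage 100; the raw ratio is
#' `Inf` as there is nothing to divide by).
#'
#' @param demand Contacts demanded per period (>= 0).
#' @param capacity Reviews deliverable per period (>= 0).
#' @return An object of class `rpm_coverage` with fields `demand`,
#'   `capacity`, `raw_coverage` (uncapped percent), `coverage` (capped at
#'   100) and `reported_coverage` (capped, rounded half-up to the nearest
#'   integer percent).
#' @examples
#' coverage(demand = 7200 / 73, capacity = 90)$reported_coverage  # 91
#' @export
coverage <- function(demand, capacity) {
  demand <- as.numeric(demand)[1]
  capacity <- as.numeric(capacity)[1]
  if (is.na(demand) || demand < 0) stop("demand must be >= 0", call. = FALSE)
  if (is.na(capacity) || capacity < 0) {
    stop("capacity must be >= 0", call. = FALSE)
  }
  raw <- if (demand > 0) 100 * capacity / demand else Inf
  capped <- min(raw, 100)
  structure(
    list(
      demand = demand,
      capacity = capacity,
      raw_coverage = raw,
      coverage = capped,
      reported_coverage = as.integer(round_half_up(capped))
    ),
    class = "rpm_coverage"
  )
}

#' @export
print.rpm_coverage <- function(x, ...) {
  cat(sprintf(
    "<coverage> demand=%.2f capacity=%.2f raw=%s%% reported=%d%%\n",
    x$demand, x$capacity,
    if (is.finite(x$raw_coverage)) sprintf("%.2f", x$raw_coverage) else "Inf",
    x$reported_coverage
  ))
  invisible(x)
}

#' Coverage of a whole scenario
#'
#' Convenience wrapper: computes demand from the scenario's cohorts (or its
#' fixed demand) and capacity from its pool, then calls [coverage()].
#'
#' @param scn A [scenario()].
#' @return An `rpm_coverage` object.
#' @export
scenario_coverage <- function(scn) {
  stopifnot(inherits(scn, "rpm_scenario"))
  coverage(projected_demand(scn), projected_capacity(scn$pool))
}

#' Back-solve demand from a known coverage percentage
#'
#' Given a pool and the coverage percentage it reportedly achieves, recover
#' the implied demand \eqn{D = 100 K / c}. This anchors scenario analysis to
#' a published coverage figure when the underlying contact fraction is not
#' known (the study clinic reported 73% baseline coverage at 3 providers,
#' 4 h/week and 10 min/review, implying about 98.6 contacts/week).
#'
#' @param coverage_pct Reported (uncapped-equivalent) coverage percent, in
#'   (0, 100].
#' @param pool The [provider_pool()] achieving that coverage.
#' @return Implied demand in contacts per period.
#' @examples
#' demand_from_coverage(73, provider_pool(3, 4, 10))  # 98.63
#' @export
demand_from_coverage <- function(coverage_pct, pool) {
  coverage_pct <- as.numeric(coverage_pct)[1]
  if (is.na(coverage_pct) || coverage_pct <= 0 || coverage_pct > 100) {
    stop("coverage_pct must be in (0, 100]", call. = FALSE)
  }
  100 * projected_capacity(pool) / coverage_pct
}

#' Rescale a known coverage percentage under a changed pool
#'
#' Holding demand fixed, coverage scales exactly with capacity, so a new
#' pool's coverage is the base percentage times \eqn{K_{new}/K_{base}},
#' capped at 100. This reproduces published what-if results anchored to a
#' baseline coverage without knowing absolute demand.
#'
#' @param base_coverage_pct Baseline coverage percent, in (0, 100].
#' @param base_pool Pool achieving the baseline coverage.
#' @param new_pool Modified pool.
#' @return An `rpm_coverage` object for the new pool at the implied demand.
#' @examples
#' # cutting review time from 10 to 8 minutes lifts 73% to 91%
#' scale_coverage(73, provider_pool(3, 4, 10),
#'                provider_pool(3, 4, 8))$reported_coverage
#' @export
scale_coverage <- function(base_coverage_pct, base_pool, new_pool) {
  d <- demand_from_coverage(base_coverage_pct, base_pool)
  coverage(d, projected_capacity(new_pool))
}

#' Project cohort populations forward
#'
#' Per-period enrolled counts under the recurrence
#' \deqn{N(k+1) = N(k)\,(1 - g) + A}
#' (graduation applies to the current census before the period's new
#' enrolments are added). With \eqn{g = 0} growth is exactly linear,
#' \eqn{N(k) = N(0) + kA}; with \eqn{g > 0} the census converges to the
#' fixed point \eqn{A / g}.
#'
#' @param cohorts A list of [cohort()] objects, a single cohort, or a
#'   [scenario()].
#' @param horizon Number of periods to return (>= 1); the first row is the
#'   current census (period 0).
#' @return A data.frame with columns `period` (0-based), `cohort`, `enrolled`.
#' @examples
#' project_population(cohort("a", 0, new_per_period = 10,
#'                           graduation_fraction = 0.5,
#'                           contact_fraction = 0), horizon = 3)
#' @export
project_population <- function(cohorts, horizon) {
  horizon <- as.numeric(horizon)[1]
  if (is.na(horizon) || horizon < 1 || horizon != round(horizon)) {
    stop("horizon must be an integer >= 1", call. = FALSE)
  }
  cl <- as_cohort_list(cohorts)
  out <- lapply(cl, function(co) {
    validate_cohort(co)
    n <- numeric(horizon)
    n[1] <- co$enrolled
    if (horizon > 1) {
      for (k in 2:horizon) {
        n[k] <- n[k - 1] * (1 - co$graduation_fraction) + co$new_per_period
      }
    }
    data.frame(period = seq_len(horizon) - 1L, cohort = co$name,
               enrolled = n, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
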