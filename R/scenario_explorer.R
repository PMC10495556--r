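# Single-axis what-if analysis: recompute coverage after changing one
# parameter, and invert the coverage equations in closed form to find the
# minimal change on each axis sufficient for capacity to meet demand.

#' Enumerate the what-if axes
#'
#' The modifiable axes, in the fixed order used by [sufficiency_table()]:
#' three capacity-side axes (provider count, hours per period, minutes per
#' review) and three demand-side axes (contact fraction, review frequency,
#' total population).
#'
#' @return Character vector of axis names.
#' @export
scenario_axes <- function() {
  c("n_providers", "hours_per_period", "minutes_per_review",
    "contact_fraction", "review_frequency", "population")
}

is_capacity_axis <- function(axis) {
  axis %in% c("n_providers", "hours_per_period", "minutes_per_review")
}

# Current value of an axis in a scenario. Demand-side axes shared by all
# cohorts report that common value; heterogeneous cohorts report NA (the
# what-if still applies a single common value).
axis_baseline <- function(scn, axis) {
  switch(axis,
    n_providers = scn$pool$n_providers,
    hours_per_period = scn$pool$hours_per_period,
    minutes_per_review = scn$pool$minutes_per_review,
    contact_fraction = {
      v <- vapply(scn$cohorts, `[[`, numeric(1), "contact_fraction")
      if (length(unique(v)) == 1L) v[1] else NA_real_
    },
    review_frequency = {
      v <- vapply(scn$cohorts, `[[`, numeric(1), "review_frequency")
      if (length(unique(v)) == 1L) v[1] else NA_real_
    },
    population = sum(vapply(scn$cohorts, function(co) {
      co$enrolled + co$new_per_period
    }, numeric(1))),
    stop("invalid axis '", axis, "'; must be one of ",
         paste(scenario_axes(), collapse = ", "), call. = FALSE)
  )
}

# Return a copy of the scenario with one axis set to new_value.
# population scales every cohort's (enrolled, new_per_period) proportionally
# to reach the requested total; contact_fraction / review_frequency set a
# common value on every cohort.
apply_modification <- function(scn, axis, new_value) {
  stopifnot(inherits(scn, "rpm_scenario"))
  if (!axis %in% scenario_axes()) {
    stop("invalid axis '", axis, "'; must be one of ",
         paste(scenario_axes(), collapse = ", "), call. = FALSE)
  }
  new_value <- as.numeric(new_value)[1]
  if (is.na(new_value)) stop("invalid value for axis ", axis, call. = FALSE)
  if (!is_capacity_axis(axis) && !is.null(scn$demand)) {
    stop("scenario has a fixed demand override; demand-side axis '", axis,
         "' is unavailable", call. = FALSE)
  }
  if (is_capacity_axis(axis)) {
    pool <- scn$pool
    pool[[axis]] <- new_value
    if (axis == "minutes_per_review") pool$reviews_per_hour <- NULL
    validate_pool(pool)
    scn$pool <- pool
    return(scn)
  }
  if (axis == "population") {
    old_total <- axis_baseline(scn, "population")
    if (old_total <= 0) {
      stop("population axis requires a positive current population",
           call. = FALSE)
    }
    s <- new_value / old_total
    if (s < 0) stop("population must be >= 0", call. = FALSE)
    scn$cohorts <- lapply(scn$cohorts, function(co) {
      co$enrolled <- co$enrolled * s
      co$new_per_period <- co$new_per_period * s
      validate_cohort(co)
      co
    })
    return(scn)
  }
  scn$cohorts <- lapply(scn$cohorts, function(co) {
    co[[axis]] <- new_value
    validate_cohort(co)
    co
  })
  scn
}

#' Evaluate a single-axis scenario modification
#'
#' Recomputes demand, capacity and coverage with exactly one axis changed,
#' and reports the change in reported coverage against the unmodified
#' scenario.
#'
#' @param scn A [scenario()].
#' @param axis One of [scenario_axes()].
#' @param new_value The modified value for that axis. For `population` this
#'   is the new total population (enrolled + new, summed over cohorts),
#'   scaled proportionally across cohorts; for `contact_fraction` and
#'   `review_frequency` it is a common value applied to every cohort.
#' @return A one-row data.frame of class `rpm_modification` with columns
#'   `axis`, `baseline_value`, `modified_value`, `resulting_coverage`
#'   (reported percent, capped) and `delta_coverage` (percentage points
#'   versus the baseline reported coverage).
#' @examples
#' base <- scenario(list(), provider_pool(3, 4, 10),
#'                  demand = demand_from_coverage(73, provider_pool(3, 4, 10)))
#' evaluate_modification(base, "minutes_per_review", 8)  # 91%, +18
#' @export
evaluate_modification <- function(scn, axis, new_value) {
  base_cov <- scenario_coverage(scn)$reported_coverage
  mod <- apply_modification(scn, axis, new_value)
  new_cov <- scenario_coverage(mod)$reported_coverage
  structure(
    data.frame(
      axis = axis,
      baseline_value = axis_baseline(scn, axis),
      modified_value = as.numeric(new_value)[1],
      resulting_coverage = new_cov,
      delta_coverage = new_cov - base_cov,
      stringsAsFactors = FALSE
    ),
    class = c("rpm_modification", "data.frame")
  )
}

#' Minimum providers for full coverage
#'
#' Smallest integer provider count whose capacity meets or exceeds demand,
#' holding hours and review time fixed: \eqn{m^* = \lceil D / (r h) \rceil}
#' with \eqn{r} the per-provider-hour review capacity. Sufficiency is judged
#' on the raw (uncapped) coverage ratio.
#'
#' @param scn A [scenario()].
#' @return Integer \eqn{m^*}; 0 when demand is zero (any headcount
#'   suffices).
#' @export
min_providers_for_full_coverage <- function(scn) {
  d <- projected_demand(scn)
  if (d == 0) return(0L)
  per_provider <- review_capacity(scn$pool) * scn$pool$hours_per_period
  as.integer(ceiling(d / per_provider - 1e-9))
}

#' Maximum minutes per review for full coverage
#'
#' Longest average review time at which capacity still meets demand:
#' \eqn{t^* = 60\,m\,h / D}. Raw coverage at \eqn{t^*} is exactly 100%.
#'
#' @param scn A [scenario()].
#' @return Minutes \eqn{t^*}; `Inf` when demand is zero.
#' @export
max_minutes_per_review <- function(scn) {
  d <- projected_demand(scn)
  if (d == 0) return(Inf)
  60 * scn$pool$n_providers * scn$pool$hours_per_period / d
}

#' Required hours per period for full coverage
#'
#' Hours each provider must allocate so capacity meets demand:
#' \eqn{h^* = D / (r m)}. Raw coverage at \eqn{h^*} is exactly 100%.
#'
#' @param scn A [scenario()].
#' @return Hours \eqn{h^*}; 0 when demand is zero.
#' @export
required_hours <- function(scn) {
  d <- projected_demand(scn)
  if (d == 0) return(0)
  d / (review_capacity(scn$pool) * scn$pool$n_providers)
}

# Conservative grid rounding: report sufficiency at slider resolution,
# rounded toward MORE capacity / LESS demand so the reported value is
# itself sufficient.
snap_up <- function(x, step) ceiling(x / step - 1e-9) * step
snap_down <- function(x, step) floor(x / step + 1e-9) * step

#' Table of minimal single-axis modifications reaching full coverage
#'
#' For each axis, the minimal change on that axis alone that makes raw
#' coverage at least 100%. Capacity-side values are exact inversions of the
#' coverage equations; continuous axes are reported at slider resolution
#' (0.1 for hours and minutes, 0.01 for the fractions, whole patients for
#' population), rounded conservatively toward more capacity. Axes that
#' cannot reach full coverage alone are flagged unreachable; when coverage
#' is already at least 100% every row reports the baseline unchanged.
#'
#' @param scn A [scenario()].
#' @param axes Axes to include, default all of [scenario_axes()] in that
#'   fixed order. Demand-side axes are skipped automatically when the
#'   scenario carries a fixed demand override.
#' @return A data.frame with columns `axis`, `baseline_value`,
#'   `sufficient_value`, `resulting_coverage` (reported, capped),
#'   `reachable` (logical), `note`.
#' @export
sufficiency_table <- function(scn, axes = scenario_axes()) {
  stopifnot(inherits(scn, "rpm_scenario"))
  bad <- setdiff(axes, scenario_axes())
  if (length(bad)) {
    stop("invalid axis: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  axes <- scenario_axes()[scenario_axes() %in% axes]
  if (!is.null(scn$demand)) {
    axes <- axes[is_capacity_axis(axes)]
  }
  d <- projected_demand(scn)
  k <- projected_capacity(scn$pool)
  already <- d <= k + 1e-12

  rows <- lapply(axes, function(ax) {
    base <- axis_baseline(scn, ax)
    if (already) {
      return(data.frame(axis = ax, baseline_value = base,
                        sufficient_value = base,
                        resulting_coverage = scenario_coverage(scn)$reported_coverage,
                        reachable = TRUE, note = "already covered",
                        stringsAsFactors = FALSE))
    }
    val <- NA_real_
    note <- ""
    reachable <- TRUE
    if (ax == "n_providers") {
      val <- as.numeric(min_providers_for_full_coverage(scn))
    } else if (ax == "hours_per_period") {
      val <- snap_up(required_hours(scn), 0.1)
    } else if (ax == "minutes_per_review") {
      val <- snap_down(max_minutes_per_review(scn), 0.1)
      if (val <= 0) {
        reachable <- FALSE
        note <- "required review time below 0.1 min"
      }
    } else if (ax == "contact_fraction") {
      denom <- sum(vapply(scn$cohorts, function(co) {
        co$review_frequency * (co$enrolled + co$new_per_period)
      }, numeric(1)))
      # d > 0 here so denom > 0
      val <- snap_down(k / denom, 0.01)
    } else if (ax == "review_frequency") {
      denom <- sum(vapply(scn$cohorts, function(co) {
        co$contact_fraction * (co$enrolled + co$new_per_period)
      }, numeric(1)))
      exact <- k / denom
      val <- snap_down(exact, 0.01)
      if (val <= 0) val <- exact  # below slider resolution: report exact
    } else if (ax == "population") {
      # demand splits into a part scaling with population and none fixed,
      # so the sufficient total is current total * K / D
      total <- axis_baseline(scn, "population")
      val <- floor(total * k / d + 1e-9)
    }
    rc <- if (reachable) {
      scenario_coverage(apply_modification(scn, ax, val))$reported_coverage
    } else NA_integer_
    data.frame(axis = ax, baseline_value = base, sufficient_value = val,
               resulting_coverage = rc, reachable = reachable, note = note,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
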