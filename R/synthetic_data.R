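# Synthetic operational-log generator. No real program logs are publicly
# deposited, so testing and calibration exercises run against synthetic
# logs that reproduce the reported statistical structure: patients shown
# growing steadily over time, binomial flagging, and a period-level
# contacted-to-flagged ratio with mean 51.8% and SD 17.1%.

#' Configure the synthetic log generator
#'
#' @param n_periods Number of periods (log rows) to generate.
#' @param initial_shown Patients shown for review in the first period.
#' @param shown_growth_per_period Additive drift in shown patients per
#'   period (may be 0 or fractional). The default growth model is linear;
#'   `growth_model = "logistic"` saturates toward `carrying_capacity`
#'   instead.
#' @param flag_probability Probability a shown patient is flagged, in
#'   `[0, 1]`.
#' @param contact_ratio_mean Mean contacted/flagged ratio (default 0.518).
#' @param contact_ratio_sd SD of the ratio (default 0.171); drawn once per
#'   period from a normal distribution truncated to `[0, 1]`.
#' @param seed Random seed; same config + seed gives a byte-identical log.
#' @param growth_model `"linear"` (default) or `"logistic"`.
#' @param carrying_capacity Saturation level for the logistic model.
#' @param start_date Date of the first period (default 2020-03-02).
#' @param period_days Days between periods (default 7, weekly).
#' @return An object of class `rpm_gen_config`.
#' @export
generator_config <- function(n_periods, initial_shown,
                             shown_growth_per_period = 0,
                             flag_probability,
                             contact_ratio_mean = 0.518,
                             contact_ratio_sd = 0.171,
                             seed = NULL,
                             growth_model = c("linear", "logistic"),
                             carrying_capacity = NULL,
                             start_date = as.Date("2020-03-02"),
                             period_days = 7L) {
  growth_model <- match.arg(growth_model)
  n_periods <- as.integer(n_periods)
  if (is.na(n_periods) || n_periods < 1) {
    stop("n_periods must be >= 1", call. = FALSE)
  }
  initial_shown <- as.numeric(initial_shown)[1]
  if (is.na(initial_shown) || initial_shown < 0) {
    stop("initial_shown must be >= 0", call. = FALSE)
  }
  flag_probability <- as.numeric(flag_probability)[1]
  if (is.na(flag_probability) || flag_probability < 0 ||
      flag_probability > 1) {
    stop("flag_probability must be in [0, 1]", call. = FALSE)
  }
  if (is.na(contact_ratio_mean) || contact_ratio_mean < 0 ||
      contact_ratio_mean > 1) {
    stop("contact_ratio_mean must be in [0, 1]", call. = FALSE)
  }
  if (is.na(contact_ratio_sd) || contact_ratio_sd < 0) {
    stop("contact_ratio_sd must be >= 0", call. = FALSE)
  }
  if (growth_model == "logistic" &&
      (is.null(carrying_capacity) || carrying_capacity <= 0)) {
    stop("logistic growth requires a positive carrying_capacity",
         call. = FALSE)
  }
  structure(
    list(n_periods = n_periods, initial_shown = initial_shown,
         shown_growth_per_period = as.numeric(shown_growth_per_period)[1],
         flag_probability = flag_probability,
         contact_ratio_mean = contact_ratio_mean,
         contact_ratio_sd = contact_ratio_sd,
         seed = seed, growth_model = growth_model,
         carrying_capacity = carrying_capacity,
         start_date = as.Date(start_date),
         period_days = as.integer(period_days)),
    class = "rpm_gen_config"
  )
}

#' Generate a synthetic operational log
#'
#' Per period `k` (0-based): `shown = round(initial + k * growth)` (or the
#' logistic analogue), `flagged ~ Binomial(shown, flag_probability)`,
#' `contacted = round(flagged * ratio)` with the ratio drawn from
#' Normal(`contact_ratio_mean`, `contact_ratio_sd`) truncated to `[0, 1]`.
#' The count inequalities `contacted <= flagged <= shown` hold by
#' construction, so the output always passes [load_log()] validation.
#'
#' @param config A [generator_config()].
#' @return An `rpm_log` data.frame (see [load_log()]).
#' @examples
#' cfg <- generator_config(10, initial_shown = 200, flag_probability = 0.3,
#'                         seed = 1)
#' generate_log(cfg)
#' @export
generate_log <- function(config) {
  stopifnot(inherits(config, "rpm_gen_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  k <- seq_len(config$n_periods) - 1
  shown_exp <- if (config$growth_model == "linear") {
    config$initial_shown + k * config$shown_growth_per_period
  } else {
    # logistic approach to the carrying capacity at the initial growth rate
    cc <- config$carrying_capacity
    n0 <- min(config$initial_shown, cc)
    g <- config$shown_growth_per_period
    if (n0 <= 0 || g <= 0) rep(n0, length(k))
    else cc / (1 + (cc / n0 - 1) * exp(-(g / n0) * k))
  }
  shown <- as.integer(round_half_up(pmax(shown_exp, 0)))
  flagged <- integer(config$n_periods)
  contacted <- integer(config$n_periods)
  for (i in seq_len(config$n_periods)) {
    flagged[i] <- stats::rbinom(1L, shown[i], config$flag_probability)
    ratio <- rtrunc01_norm(1L, config$contact_ratio_mean,
                           config$contact_ratio_sd)
    contacted[i] <- as.integer(round_half_up(flagged[i] * ratio))
  }
  df <- data.frame(
    period_start = config$start_date + (seq_len(config$n_periods) - 1L) *
      config$period_days,
    shown = shown, flagged = flagged, contacted = contacted
  )
  validate_log_df(df, where = "generated log")
  class(df) <- c("rpm_log", "data.frame")
  df
}

#' Built-in scenario presets
#'
#' `"baseline_study"` reproduces the study clinic's published parameters:
#' three CDCESs at 4 h/week and 10 min/review (capacity 72 reviews/week),
#' with the three monitored cohorts — the pilot study (n = 135, weekly
#' review), the main study (n = 133, weekly) and the public-insurance CGM
#' program (n = 94, monthly, `review_frequency = 0.25`). Contact fractions
#' are deliberately left unset (`NA`): the study never published its
#' baseline contact fraction, and silently inventing one would fabricate
#' data — set them (or use [demand_from_coverage()] to anchor demand)
#' before computing coverage. `"toy"` is a small hand-checkable scenario
#' (one cohort, N = 38, A = 2, f = 1, p = 0.25, demand 10 against capacity
#' 12).
#'
#' @param preset_name `"baseline_study"` or `"toy"`.
#' @return A [scenario()].
#' @examples
#' projected_capacity(generate_scenario("baseline_study")$pool)  # 72
#' scenario_coverage(generate_scenario("toy"))
#' @export
generate_scenario <- function(preset_name) {
  presets <- c("baseline_study", "toy")
  if (!is.character(preset_name) || length(preset_name) != 1 ||
      !preset_name %in% presets) {
    stop("unknown preset '", paste(preset_name, collapse = ","),
         "'; available presets: ", paste(presets, collapse = ", "),
         call. = FALSE)
  }
  if (preset_name == "baseline_study") {
    scenario(
      cohorts = list(
        cohort("pilot_4T", enrolled = 135, review_frequency = 1,
               contact_fraction = NA_real_),
        cohort("study_4T", enrolled = 133, review_frequency = 1,
               contact_fraction = NA_real_),
        cohort("TIPS", enrolled = 94, review_frequency = 0.25,
               contact_fraction = NA_real_)
      ),
      pool = provider_pool(3, 4, 10),
      period_label = "week"
    )
  } else {
    scenario(
      cohorts = list(
        cohort("toy", enrolled = 38, new_per_period = 2,
               review_frequency = 1, contact_fraction = 0.25)
      ),
      pool = provider_pool(1, 2, 10),
      period_label = "week"
    )
  }
}
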