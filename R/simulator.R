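# Monte-Carlo workload simulator. The deterministic model ignores demand
# variance; here flagged counts are binomial in the patients shown, and the
# contacted-to-flagged ratio is drawn per period from a normal distribution
# truncated to [0, 1], calibrated by default to the published period-level
# statistics (mean 51.8%, SD 17.1%).

# Inverse-CDF draw from Normal(mean, sd) truncated to [0, 1]; sd = 0 is the
# degenerate point mass at the mean.
rtrunc01_norm <- function(n, mean, sd) {
  if (sd == 0) return(rep(min(max(mean, 0), 1), n))
  lo <- stats::pnorm((0 - mean) / sd)
  hi <- stats::pnorm((1 - mean) / sd)
  u <- stats::runif(n, lo, hi)
  x <- mean + sd * stats::qnorm(u)
  pmin(pmax(x, 0), 1)
}

#' Configure a workload simulation
#'
#' @param n_periods Periods to simulate per replicate (>= 1).
#' @param cohorts A list of [cohort()] objects (or one cohort); their review
#'   frequencies and population dynamics drive how many patients are shown
#'   for review each period. Contact fractions are not used here — contact
#'   arises from the flag/ratio mechanism instead.
#' @param flag_probability Probability a shown patient is flagged in a
#'   period, in `[0, 1]`. Scalar, or one value per cohort.
#' @param contact_ratio_mean Mean of the per-period contacted-to-flagged
#'   ratio (fraction). Default 0.518, the study program's published mean.
#' @param contact_ratio_sd Standard deviation of that ratio. Default 0.171,
#'   the published SD. The ratio is drawn once per period from a normal
#'   distribution truncated to `[0, 1]`.
#' @param seed Random seed; fixed seed gives bit-reproducible output.
#' @param n_replicates Monte-Carlo replicates (>= 1).
#' @return An object of class `rpm_sim_config`.
#' @export
simulation_config <- function(n_periods, cohorts, flag_probability,
                              contact_ratio_mean = 0.518,
                              contact_ratio_sd = 0.171,
                              seed = NULL, n_replicates = 1) {
  if (inherits(cohorts, "rpm_cohort")) cohorts <- list(cohorts)
  lapply(cohorts, validate_cohort)
  flag_probability <- as.numeric(flag_probability)
  if (!length(flag_probability) %in% c(1L, length(cohorts))) {
    stop("flag_probability must be scalar or one value per cohort",
         call. = FALSE)
  }
  if (any(is.na(flag_probability)) || any(flag_probability < 0) ||
      any(flag_probability > 1)) {
    stop("flag_probability must be in [0, 1]", call. = FALSE)
  }
  if (is.na(contact_ratio_mean) || contact_ratio_mean < 0 ||
      contact_ratio_mean > 1) {
    stop("contact_ratio_mean must be in [0, 1]", call. = FALSE)
  }
  if (is.na(contact_ratio_sd) || contact_ratio_sd < 0) {
    stop("contact_ratio_sd must be >= 0", call. = FALSE)
  }
  n_periods <- as.integer(n_periods)
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_periods) || n_periods < 1) {
    stop("n_periods must be >= 1", call. = FALSE)
  }
  if (is.na(n_replicates) || n_replicates < 1) {
    stop("n_replicates must be >= 1", call. = FALSE)
  }
  structure(
    list(n_periods = n_periods, cohorts = cohorts,
         flag_probability = flag_probability,
         contact_ratio_mean = contact_ratio_mean,
         contact_ratio_sd = contact_ratio_sd,
         seed = seed, n_replicates = n_replicates),
    class = "rpm_sim_config"
  )
}

#' Simulate per-period workload against a provider pool
#'
#' Each period: the patients shown for review follow the deterministic
#' population trajectory (`round(f_i * N_i(k))` summed over cohorts); the
#' flagged count is Binomial(shown, flag_probability), drawn per cohort; the
#' contacted count is the flagged count times a truncated-normal ratio draw,
#' rounded half-up. Contacts exceeding the period's review capacity join a
#' FIFO backlog served ahead of new contacts in later periods. Draws occur
#' in a fixed order (flagged first, then the ratio, within each period) from
#' a single seeded generator, so a fixed seed reproduces the run exactly.
#'
#' @param config An [simulation_config()].
#' @param pool A [provider_pool()] supplying per-period review capacity.
#' @return A data.frame with one row per (replicate, period): columns
#'   `replicate`, `period` (1-based), `shown`, `flagged`, `contacted`,
#'   `capacity`, `served`, `shortfall` (`max(0, contacted - capacity)`) and
#'   `backlog` (contacts still waiting at period end).
#' @export
simulate_workload <- function(config, pool) {
  stopifnot(inherits(config, "rpm_sim_config"))
  validate_pool(pool)
  if (!is.null(config$seed)) set.seed(config$seed)
  k_cap <- projected_capacity(pool)
  nco <- length(config$cohorts)
  fp <- rep(config$flag_probability, length.out = nco)
  freq <- vapply(config$cohorts, `[[`, numeric(1), "review_frequency")
  # shown per cohort per period, fixed by the population trajectory
  shown_mat <- matrix(0L, nrow = config$n_periods, ncol = nco)
  for (j in seq_len(nco)) {
    tr <- project_population(config$cohorts[[j]], config$n_periods)
    shown_mat[, j] <- as.integer(round_half_up(freq[j] * tr$enrolled))
  }
  reps <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    shown <- integer(config$n_periods)
    flagged <- integer(config$n_periods)
    contacted <- integer(config$n_periods)
    served <- numeric(config$n_periods)
    shortfall <- numeric(config$n_periods)
    backlog <- numeric(config$n_periods)
    carry <- 0
    for (k in seq_len(config$n_periods)) {
      fl <- 0L
      for (j in seq_len(nco)) {
        fl <- fl + stats::rbinom(1L, shown_mat[k, j], fp[j])
      }
      ratio <- rtrunc01_norm(1L, config$contact_ratio_mean,
                             config$contact_ratio_sd)
      ct <- as.integer(round_half_up(fl * ratio))
      queue <- carry + ct
      sv <- min(k_cap, queue)
      carry <- queue - sv
      shown[k] <- sum(shown_mat[k, ])
      flagged[k] <- fl
      contacted[k] <- ct
      served[k] <- sv
      shortfall[k] <- max(0, ct - k_cap)
      backlog[k] <- carry
    }
    reps[[r]] <- data.frame(
      replicate = r, period = seq_len(config$n_periods),
      shown = shown, flagged = flagged, contacted = contacted,
      capacity = k_cap, served = served, shortfall = shortfall,
      backlog = backlog
    )
  }
  out <- do.call(rbind, reps)
  rownames(out) <- NULL
  out
}

#' Summarise simulated shortfall and backlog
#'
#' @param sim Output of [simulate_workload()].
#' @return A list with `per_replicate` (data.frame: `replicate`,
#'   `any_shortfall`, `prop_periods_shortfall`, `mean_backlog`,
#'   `peak_backlog`, `final_backlog`) and `pooled` (list:
#'   `prob_any_shortfall` — fraction of replicates with at least one
#'   shortfall period, `prop_periods_shortfall`, `mean_backlog`,
#'   `peak_backlog`, and `coverage_quantiles` — quantiles of the per-period
#'   capped coverage of contacts by capacity).
#' @export
shortfall_summary <- function(sim) {
  stopifnot(is.data.frame(sim),
            all(c("replicate", "shortfall", "backlog", "capacity",
                  "contacted") %in% names(sim)))
  reps <- split(sim, sim$replicate)
  per <- do.call(rbind, lapply(reps, function(df) {
    data.frame(
      replicate = df$replicate[1],
      any_shortfall = any(df$shortfall > 0),
      prop_periods_shortfall = mean(df$shortfall > 0),
      mean_backlog = mean(df$backlog),
      peak_backlog = max(df$backlog),
      final_backlog = df$backlog[nrow(df)]
    )
  }))
  rownames(per) <- NULL
  period_cov <- ifelse(sim$contacted > 0,
                       pmin(100, 100 * sim$capacity / sim$contacted), 100)
  list(
    per_replicate = per,
    pooled = list(
      prob_any_shortfall = mean(per$any_shortfall),
      prop_periods_shortfall = mean(sim$shortfall > 0),
      mean_backlog = mean(sim$backlog),
      peak_backlog = max(sim$backlog),
      coverage_quantiles = stats::quantile(
        period_cov, c(0.05, 0.25, 0.5, 0.75, 0.95))
    )
  )
}
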