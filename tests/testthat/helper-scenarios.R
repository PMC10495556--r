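# Shared fixtures: the study-anchored baseline and randomized small
# scenarios for property tests.

# Baseline anchored to the published figures: 3 providers x 4 h/week at
# 10 min/review (72 reviews/week) reportedly covering 73% of demand, so the
# implied demand is 7200/73 ~ 98.63 contacts/week.
baseline_pool <- function() provider_pool(3, 4, 10)

anchored_baseline <- function() {
  pool <- baseline_pool()
  scenario(list(), pool, demand = demand_from_coverage(73, pool))
}

# Random small scenario with explicit cohorts (all parameters set), for
# solver/grid-search comparisons. Deterministic in i.
random_scenario <- function(i) {
  set.seed(7000 + i)
  n_cohorts <- sample(1:3, 1)
  cohorts <- lapply(seq_len(n_cohorts), function(j) {
    cohort(
      name = paste0("c", j),
      enrolled = sample(5:80, 1),
      new_per_period = sample(0:5, 1),
      graduation_fraction = stats::runif(1, 0, 0.2),
      review_frequency = sample(c(0.25, 0.5, 1), 1),
      contact_fraction = stats::runif(1, 0.05, 0.9)
    )
  })
  pool <- provider_pool(
    n_providers = sample(1:6, 1),
    hours_per_period = sample(seq(1, 8, by = 0.5), 1),
    minutes_per_review = sample(2:20, 1)
  )
  scenario(cohorts, pool)
}

# Tiny valid log for IO tests.
tiny_log <- function() {
  structure(
    data.frame(
      period_start = as.Date(c("2021-01-04", "2021-01-11", "2021-01-18")),
      shown = c(50L, 52L, 55L),
      flagged = c(20L, 26L, 23L),
      contacted = c(10L, 13L, 12L)
    ),
    class = c("rpm_log", "data.frame")
  )
}
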