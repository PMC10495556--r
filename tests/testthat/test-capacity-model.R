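test_that("projected demand multiplies cadence, contact fraction and population", {
  # empty population
  expect_equal(projected_demand(cohort("z", 0, 0, contact_fraction = 0.7)), 0)
  # f * p * (N + A) = 1 * 0.25 * 40
  expect_equal(
    projected_demand(cohort("a", 38, 2, contact_fraction = 0.25)),
    10)
  # additive over cohorts, cadence scales linearly: 5 + 5
  expect_equal(
    projected_demand(list(
      cohort("w", 10, contact_fraction = 0.5, review_frequency = 1),
      cohort("m", 40, contact_fraction = 0.5, review_frequency = 0.25))),
    10)
})

test_that("demand is additive and homogeneous of degree 1 in population", {
  for (i in 1:25) {
    scn <- random_scenario(i)
    d <- projected_demand(scn$cohorts)
    # additivity: sum of single-cohort demands
    expect_equal(sum(vapply(scn$cohorts, projected_demand, numeric(1))), d)
    # doubling every cohort's population doubles demand exactly
    doubled <- lapply(scn$cohorts, function(co) {
      co$enrolled <- 2 * co$enrolled
      co$new_per_period <- 2 * co$new_per_period
      co
    })
    expect_equal(projected_demand(doubled), 2 * d)
  }
})

test_that("projected capacity is reviews/hour x providers x hours", {
  expect_equal(projected_capacity(provider_pool(3, 4, 10)), 72)
  expect_equal(projected_capacity(provider_pool(1, 1, 60)), 1)
  expect_equal(projected_capacity(provider_pool(5, 4, 10)), 120)
  # explicit reviews-per-hour override replaces the 60/t derivation
  expect_equal(
    projected_capacity(provider_pool(3, 4, 10, reviews_per_hour = 5)), 60)
})

test_that("capacity is invariant under trading providers for hours", {
  for (m in c(1, 2, 4)) {
    for (cfac in c(2, 4)) {
      k1 <- projected_capacity(provider_pool(m, 8, 12))
      k2 <- projected_capacity(provider_pool(m * cfac, 8 / cfac, 12))
      expect_equal(k1, k2)
    }
  }
})

test_that("parameter invariants are enforced", {
  expect_error(cohort("x", -1, contact_fraction = 0.5), "enrolled")
  expect_error(cohort("x", 1, contact_fraction = 1.5), "contact_fraction")
  expect_error(cohort("x", 1, review_frequency = 0, contact_fraction = 0.5),
               "review_frequency")
  expect_error(cohort("x", 1, graduation_fraction = 2,
                      contact_fraction = 0.5), "graduation_fraction")
  expect_error(provider_pool(0, 4, 10), "n_providers")
  expect_error(provider_pool(2.5, 4, 10), "n_providers")
  expect_error(provider_pool(3, 0, 10), "hours_per_period")
  expect_error(provider_pool(3, 4, -1), "minutes_per_review")
  expect_error(coverage(-1, 10), "demand")
  # unset contact fraction is storable but refuses demand computation
  placeholder <- cohort("p", 10)
  expect_error(projected_demand(placeholder), "contact_fraction")
})

test_that("coverage is capacity over demand, capped at 100, rounded half-up", {
  # the anchored baseline: 72 reviews against ~98.6 contacts -> 73%
  cv <- coverage(98.63, 72)
  expect_equal(cv$reported_coverage, 73L)
  # 8-minute scenario: K = 90 -> 91.25% raw -> 91 reported
  cv8 <- coverage(98.63, 90)
  expect_equal(cv8$raw_coverage, 100 * 90 / 98.63)
  expect_equal(cv8$reported_coverage, 91L)
  # no demand is fully covered
  cv0 <- coverage(0, 0)
  expect_equal(cv0$coverage, 100)
  expect_equal(cv0$reported_coverage, 100L)
  expect_true(is.infinite(cv0$raw_coverage))
  # capped coverage never exceeds 100 and never exceeds the raw ratio
  cvbig <- coverage(10, 50)
  expect_equal(cvbig$coverage, 100)
  expect_equal(cvbig$raw_coverage, 500)
  # half-up reporting (72.5 -> 73, where round-half-even would give 72)
  expect_equal(coverage(100, 72.5)$reported_coverage, 73L)
})

test_that("coverage is monotone in capacity and demand and bounded by 100", {
  set.seed(11)
  for (i in 1:50) {
    d <- stats::runif(1, 1, 200)
    k <- stats::runif(1, 0, 300)
    cv <- coverage(d, k)
    expect_lte(cv$coverage, 100)
    expect_lte(cv$coverage, cv$raw_coverage)
    # non-decreasing in capacity
    expect_gte(coverage(d, k * 1.1)$coverage, cv$coverage)
    # non-increasing in demand
    expect_lte(coverage(d * 1.1, k)$coverage, cv$coverage)
  }
})

test_that("scale_coverage reproduces the published what-if percentages", {
  base <- baseline_pool()
  expect_equal(scale_coverage(73, base, provider_pool(3, 4, 8))$reported_coverage, 91L)
  expect_equal(scale_coverage(73, base, provider_pool(5, 4, 10))$reported_coverage, 100L)
  expect_equal(scale_coverage(73, base, base)$reported_coverage, 73L)
  expect_error(scale_coverage(0, base, base), "coverage_pct")
})

test_that("scale_coverage agrees with coverage() at any consistent demand", {
  set.seed(23)
  for (i in 1:30) {
    base_pool <- provider_pool(sample(1:6, 1), stats::runif(1, 1, 8),
                               stats::runif(1, 3, 20))
    new_pool <- provider_pool(sample(1:6, 1), stats::runif(1, 1, 8),
                              stats::runif(1, 3, 20))
    base_pct <- stats::runif(1, 20, 100)
    # any (D, K_base) pair consistent with the base percentage gives the
    # same result as rescaling the percentage directly
    d <- 100 * projected_capacity(base_pool) / base_pct
    direct <- coverage(d, projected_capacity(new_pool))
    scaled <- scale_coverage(base_pct, base_pool, new_pool)
    expect_equal(scaled$coverage, direct$coverage, tolerance = 1e-9)
  }
})

test_that("population projection follows the graduation/enrolment recurrence", {
  # steady state: no graduation, no enrolment
  tr <- project_population(
    cohort("s", 100, contact_fraction = 0.1), horizon = 5)
  expect_equal(tr$enrolled, rep(100, 5))
  expect_equal(tr$period, 0:4)
  # hand recurrence: N(k+1) = N(k)/2 + 10 from N(0) = 0
  tr2 <- project_population(
    cohort("g", 0, new_per_period = 10, graduation_fraction = 0.5,
           contact_fraction = 0.1), horizon = 3)
  expect_equal(tr2$enrolled, c(0, 10, 15))
  # convergence to the fixed point A / g
  tr3 <- project_population(
    cohort("fp", 100, new_per_period = 10, graduation_fraction = 0.1,
           contact_fraction = 0.1), horizon = 200)
  expect_equal(tr3$enrolled[200], 100, tolerance = 1e-6)
  # at the fixed point the census never moves
  expect_true(all(abs(tr3$enrolled - 100) < 1e-6))
  expect_error(project_population(cohort("x", 1, contact_fraction = 0.5), 0),
               "horizon")
})

test_that("with no graduation the trajectory grows exactly linearly", {
  tr <- project_population(
    cohort("lin", 40, new_per_period = 2.5, contact_fraction = 0.3),
    horizon = 12)
  expect_equal(tr$enrolled, 40 + (0:11) * 2.5)
})
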