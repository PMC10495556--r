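test_that("log CSV writing and loading are exact inverses", {
  log <- tiny_log()
  path <- withr::local_tempfile(fileext = ".csv")
  write_log(log, path)
  lines <- readLines(path)
  expect_equal(lines[1], "period_start,shown,flagged,contacted")
  back <- load_log(path)
  expect_equal(back$period_start, log$period_start)
  expect_equal(back$shown, log$shown)
  expect_equal(back$flagged, log$flagged)
  expect_equal(back$contacted, log$contacted)
  # writing the reloaded log reproduces the file byte-for-byte
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_log(back, path2)
  expect_identical(readLines(path2), lines)
})

test_that("header-only logs load as zero rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("period_start,shown,flagged,contacted", path)
  expect_equal(nrow(load_log(path)), 0L)
})

test_that("malformed logs are rejected with the offending line number", {
  write_lines <- function(...) {
    p <- withr::local_tempfile(fileext = ".csv",
                               .local_envir = parent.frame())
    writeLines(c("period_start,shown,flagged,contacted", ...), p)
    p
  }
  # contacted > flagged on data line 3
  p1 <- write_lines("2021-01-04,50,20,10", "2021-01-11,50,20,25")
  expect_error(load_log(p1), "line 3")
  # flagged > shown
  p2 <- write_lines("2021-01-04,10,20,5")
  expect_error(load_log(p2), "count inequality")
  # dates out of order
  p3 <- write_lines("2021-01-11,50,20,10", "2021-01-04,50,20,10")
  expect_error(load_log(p3), "strictly increasing")
  # unparseable count
  p4 <- write_lines("2021-01-04,abc,20,10")
  expect_error(load_log(p4), "malformed shown at line 2")
  # missing column
  p5 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("period_start,shown,flagged", "2021-01-04,50,20"), p5)
  expect_error(load_log(p5), "expected header")
})

test_that("ratio statistics match hand-computed means and sample SDs", {
  log <- tiny_log()
  log$flagged <- c(10L, 10L, 10L)
  log$contacted <- c(5L, 5L, 5L)
  rs <- ratio_statistics(log)
  expect_equal(rs$mean_ratio, 50.0)
  expect_equal(rs$sd_ratio, 0.0)
  expect_equal(rs$n_excluded, 0L)
  # ratios 0.4 and 0.6: mean 50.0, sample SD 14.1 (to one decimal)
  log2 <- tiny_log()[1:2, ]
  log2$flagged <- c(10L, 10L)
  log2$contacted <- c(4L, 6L)
  rs2 <- ratio_statistics(log2)
  expect_equal(rs2$mean_ratio, 50.0)
  expect_equal(rs2$sd_ratio, 14.1)
  # zero-flagged periods are excluded and counted
  log3 <- tiny_log()
  log3$flagged <- c(10L, 0L, 10L)
  log3$contacted <- c(4L, 0L, 6L)
  rs3 <- ratio_statistics(log3)
  expect_equal(rs3$n_periods, 2L)
  expect_equal(rs3$n_excluded, 1L)
  expect_equal(rs3$mean_ratio, 50.0)
  # no usable periods at all
  log4 <- tiny_log()
  log4$flagged <- c(0L, 0L, 0L)
  log4$contacted <- c(0L, 0L, 0L)
  expect_error(ratio_statistics(log4), "no periods")
})

test_that("ratio statistics are invariant to reordering and common scaling", {
  cfg <- generator_config(40, initial_shown = 300, flag_probability = 0.4,
                          seed = 12)
  log <- generate_log(cfg)
  rs <- ratio_statistics(log)
  # permute rows, re-sort by date, recompute
  perm <- log[sample(nrow(log)), ]
  perm <- perm[order(perm$period_start), ]
  expect_equal(ratio_statistics(perm), rs)
  # scaling flagged and contacted by a common integer leaves ratios alone
  scaled <- log
  scaled$shown <- log$shown * 7L
  scaled$flagged <- log$flagged * 7L
  scaled$contacted <- log$contacted * 7L
  expect_equal(ratio_statistics(scaled)$mean_ratio, rs$mean_ratio)
  expect_equal(ratio_statistics(scaled)$sd_ratio, rs$sd_ratio)
})

test_that("projection versus actual flags over- and under-prediction", {
  # a scenario back-fitted to a constant log predicts it exactly
  log <- tiny_log()
  log$shown <- rep(60L, 3)
  log$flagged <- rep(30L, 3)
  log$contacted <- rep(12L, 3)
  scn <- scenario(cohort("c", enrolled = 60, review_frequency = 1,
                         contact_fraction = 0.2),
                  provider_pool(1, 4, 10))
  ev <- projection_vs_actual(log, scn)
  expect_equal(ev$comparison$projected_contacted, rep(12, 3))
  expect_equal(unname(ev$mape["contacted"]), 0)
  # doubling demand overpredicts by exactly 100% each period
  scn2 <- scenario(cohort("c", enrolled = 60, review_frequency = 1,
                          contact_fraction = 0.4),
                   provider_pool(1, 4, 10))
  ev2 <- projection_vs_actual(log, scn2)
  expect_equal(ev2$comparison$pct_error_contacted, rep(100, 3))
  expect_equal(unname(ev2$mape["contacted"]), 100)
  # supplying a flag probability adds the flagged comparison
  ev3 <- projection_vs_actual(log, scn, flag_probability = 0.5)
  expect_equal(ev3$comparison$projected_flagged, rep(30, 3))
  expect_equal(unname(ev3$mape["flagged"]), 0)
})

test_that("projection error against generated logs stays within noise", {
  # the generator's mean demand equals f * q * r_mean * shown; a matching
  # scenario's per-period relative error is driven by the ratio noise
  # (SD/mean ~ 33%, so mean absolute relative error well under 50%)
  cfg <- generator_config(120, initial_shown = 300, flag_probability = 0.4,
                          seed = 21)
  log <- generate_log(cfg)
  scn <- scenario(cohort("match", enrolled = 300, review_frequency = 1,
                         contact_fraction = 0.4 * 0.518),
                  provider_pool(3, 4, 10))
  ev <- projection_vs_actual(log, scn)
  expect_lt(unname(ev$mape["contacted"]), 50)
})

test_that("calibration fitting recovers deterministic and simulated logs", {
  # deterministic fixture: flagged/shown = 0.3 everywhere
  log <- tiny_log()
  log$shown <- c(100L, 100L, 100L)
  log$flagged <- c(30L, 30L, 30L)
  log$contacted <- c(15L, 15L, 15L)
  cal <- fit_calibration(log)
  expect_equal(cal$flag_probability, 0.3)
  expect_equal(cal$contact_ratio_mean, 0.5)
  expect_equal(cal$contact_ratio_sd, 0)
  # shown = 0 rows are excluded with a warning
  log2 <- tiny_log()
  log2$shown <- c(0L, 100L, 100L)
  log2$flagged <- c(0L, 30L, 30L)
  log2$contacted <- c(0L, 15L, 15L)
  expect_warning(cal2 <- fit_calibration(log2), "shown = 0")
  expect_equal(cal2$flag_probability, 0.3)
  # round trip: generate at known parameters, refit, recover them
  # (averaged over seeds so the tolerance sits at ~3 standard errors:
  # a single 500-period log estimates the ratio mean to only +/-0.8 points)
  fits <- lapply(401:405, function(seed) {
    cfg <- generator_config(500, initial_shown = 250,
                            flag_probability = 0.35,
                            contact_ratio_mean = 0.518,
                            contact_ratio_sd = 0.171, seed = seed)
    fit_calibration(generate_log(cfg))
  })
  avg <- function(field) mean(vapply(fits, `[[`, numeric(1), field))
  expect_lt(abs(avg("flag_probability") - 0.35), 0.02)
  expect_lt(abs(100 * avg("contact_ratio_mean") - 51.8), 1.0)
  expect_lt(abs(100 * avg("contact_ratio_sd") - 17.1), 1.5)
})
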