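test_that("one-minute binning averages non-overlapping 60-s blocks", {
  # constant signal, 255 min at 10 Hz
  t <- seq(0.1, 255 * 60, by = 0.1)
  b <- bin_one_minute(t, rep(65, length(t)))
  expect_length(b, 255)
  expect_true(all(b == 65))

  # bin count is floor(duration / 60 s) regardless of rate
  t2 <- seq(0.5, 130 * 60, by = 0.5)
  expect_length(bin_one_minute(t2, rep(1, length(t2))), 130)

  # per-bin arithmetic means
  t3 <- seq(0.1, 120, by = 0.1)
  v3 <- rep(c(59, 71), each = 600)
  expect_equal(bin_one_minute(t3, v3), c(59, 71))

  expect_length(bin_one_minute(numeric(), numeric()), 0)
  expect_length(bin_one_minute(c(1, 2, 3), c(5, 5, 5)), 0)  # < one full bin
  expect_error(bin_one_minute(c(2, 1), c(0, 0)))
})

test_that("binning is consistent across acquisition rates", {
  f <- function(t) 65 + 8 * sin(2 * pi * t / 600)
  t_hi <- seq(0.001, 600, by = 0.001)   # 1000 Hz
  t_lo <- seq(0.1, 600, by = 0.1)       # 10 Hz
  expect_equal(bin_one_minute(t_hi, f(t_hi)), bin_one_minute(t_lo, f(t_lo)),
               tolerance = 1e-3)
})

test_that("time-in-range boundaries are inclusive as defined", {
  r <- time_in_range(c(59, 60, 70, 71))
  expect_equal(r$pct_lt60, 25)
  expect_equal(r$pct_60_70, 50)
  expect_equal(r$pct_gt70, 25)

  r2 <- time_in_range(rep(65, 10))
  expect_equal(r2$pct_60_70, 100)

  r3 <- time_in_range(c(75, 85))
  expect_equal(r3$pct_70_80, 50)
  expect_equal(r3$pct_gt80, 50)
  # 80 itself belongs to the 70-80 band
  expect_equal(time_in_range(c(80))$pct_70_80, 100)

  expect_error(time_in_range(numeric()))
})

test_that("band percentages always partition 100%", {
  set.seed(99)
  for (i in 1:20) {
    bins <- runif(sample(1:300, 1), 30, 110)
    r <- time_in_range(bins)
    expect_equal(r$pct_lt60 + r$pct_60_70 + r$pct_gt70, 100, tolerance = 1e-9)
    expect_equal(r$pct_gt70, r$pct_70_80 + r$pct_gt80, tolerance = 1e-9)
  }
})

test_that("intervention statistics reproduce the rate arithmetic", {
  iv <- data.frame(time_s = seq(100, by = 420, length.out = 36),
                   kind = rep(c("fluid_bolus", "ne_increase"), 18))
  s <- intervention_stats(iv, window_s = c(0, 255 * 60))
  expect_equal(s$interventions_per_hour, 36 / (255 / 60), tolerance = 1e-9)
  expect_equal(round(s$interventions_per_hour, 2), 8.47)

  iv2 <- data.frame(time_s = 1:12,
                    kind = c(rep("fluid_bolus", 6), rep("test_bolus", 2),
                             rep("ne_increase", 3), "ne_decrease"))
  s2 <- intervention_stats(iv2, window_s = c(0, 3600))
  expect_equal(s2$pct_boluses, 100 * 8 / 12, tolerance = 1e-9)
  expect_equal(s2$pct_titrations, 100 * 4 / 12, tolerance = 1e-9)

  s3 <- intervention_stats(iv2[0, ], window_s = c(0, 3600))
  expect_equal(s3$interventions_per_hour, 0)
  expect_true(is.na(s3$pct_boluses))
})

test_that("cohort medians and quartiles match a brute-force oracle", {
  # the packaged five-animal hypotension column
  x <- c(16.9, 8.6, 5.1, 15.3, 26.3)
  cs <- cohort_summary(data.frame(pct_lt60 = x))
  expect_equal(cs$median, 15.3)
  expect_equal(cs$q1, 8.6)
  expect_equal(cs$q3, 16.9)

  expect_equal(unlist(cohort_summary(data.frame(v = 1:5))[, c("q1", "median", "q3")],
                      use.names = FALSE), c(2, 3, 4))

  single <- cohort_summary(data.frame(v = 7.5))
  expect_equal(single$median, 7.5)
  expect_equal(single$q1, 7.5)
  expect_equal(single$q3, 7.5)

  set.seed(5)
  for (i in 1:25) {
    v <- runif(sample(2:50, 1), 0, 100)
    cs <- cohort_summary(data.frame(v = v))
    expect_equal(cs$q1, brute_quantile(v, 0.25), tolerance = 1e-12)
    expect_equal(cs$median, brute_quantile(v, 0.5), tolerance = 1e-12)
    expect_equal(cs$q3, brute_quantile(v, 0.75), tolerance = 1e-12)
  }
})

test_that("the packaged cohort fixture reproduces the published summary", {
  fx <- cohort_fixture()
  expect_equal(nrow(fx), 5)
  cs <- cohort_summary(fx[, -1])
  lt60 <- cs[cs$field == "pct_lt60", ]
  expect_equal(c(lt60$median, lt60$q1, lt60$q3), c(15.3, 8.6, 16.9))
  # each animal's bands sum to 100 as printed
  expect_true(all(abs(rowSums(fx[, -1]) - 100) <= 0.15))
})

test_that("exclusion screens fire on the defined hemodynamic criteria", {
  mk_vitals <- function(map) data.frame(time_s = seq_along(map), pap_mmHg = map)
  phases <- list(setup = c(0, 1800), t0 = 1800)
  ne_ok <- data.frame(time_s = 0, ne_rate = 0.02)

  # 301 s below 20 mmHg -> expiration
  v <- mk_vitals(c(rep(65, 100), rep(15, 302), rep(65, 100)))
  expect_true("expiration" %in% exclusion_screen(v, ne_ok, phases))
  # 4 min below -> no flag
  v2 <- mk_vitals(c(rep(65, 100), rep(15, 240), rep(65, 100)))
  expect_length(exclusion_screen(v2, ne_ok, phases), 0)

  # two 6-min setup stretches above 0.1 -> cumulative 12 min -> flag
  ne <- data.frame(time_s = c(0, 100, 460, 800, 1160, 1800),
                   ne_rate = c(0.02, 0.12, 0.02, 0.12, 0.02, 0.02))
  expect_true("setup_pressor" %in%
                exclusion_screen(mk_vitals(rep(65, 10)), ne, phases))

  # 0.05 at time zero -> below the 0.06 baseline threshold, no flag
  ne2 <- data.frame(time_s = c(0, 1700), ne_rate = c(0.02, 0.05))
  expect_false("baseline_pressor" %in%
                 exclusion_screen(mk_vitals(rep(65, 10)), ne2, phases))
  ne3 <- data.frame(time_s = c(0, 1700), ne_rate = c(0.02, 0.07))
  expect_true("baseline_pressor" %in%
                exclusion_screen(mk_vitals(rep(65, 10)), ne3, phases))

  expect_error(exclusion_screen(mk_vitals(rep(65, 10)), ne_ok, list()),
               "phases")
})
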