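cfg <- default_cfg()

test_that("MAP zones partition the axis with inclusive 60-70 band", {
  expect_identical(classify_map(60, cfg), "normo")
  expect_identical(classify_map(70, cfg), "normo")
  expect_identical(classify_map(70.01, cfg), "hyper")
  expect_identical(classify_map(50, cfg), "moderate_hypo")
  expect_identical(classify_map(49.99, cfg), "severe_hypo")
  expect_identical(classify_map(0, cfg), "severe_hypo")
  # every finite MAP lands in exactly one zone
  for (m in seq(0, 120, by = 0.25)) {
    z <- classify_map(m, cfg)
    expect_true(z %in% c("severe_hypo", "moderate_hypo", "normo", "hyper"))
    manual <- if (m < 50) "severe_hypo" else if (m < 60) "moderate_hypo"
      else if (m <= 70) "normo" else "hyper"
    expect_identical(z, manual)
  }
  expect_error(classify_map(NaN, cfg))
  expect_error(classify_map(Inf, cfg))
  expect_error(classify_map(-1, cfg))
})

test_that("titration step matches independent hand arithmetic", {
  # 1 x 0.0072 x |55-65| x sqrt(0.04) = 0.0072 * 10 * 0.2
  expect_equal(titration_delta(55, 0.04, 1, cfg), 0.0144)
  # 2 x 0.0072 x |75-65| x sqrt(0.09) = 2 * 0.0072 * 10 * 0.3
  expect_equal(titration_delta(75, 0.09, 2, cfg), 0.0432)
  expect_equal(titration_delta(65, 0.3, 1, cfg), 0)
  expect_error(titration_delta(55, -0.1, 1, cfg))
})

test_that("titration step is monotone in MAP deviation and NE rate, 0 at target", {
  for (ne in c(0.05, 0.1, 0.5)) {
    d <- sapply(seq(65, 95, by = 5), function(m) titration_delta(m, ne, 1, cfg))
    expect_true(all(diff(d) >= 0))
  }
  for (m in c(45, 55, 75)) {
    d <- sapply(seq(0.05, 1, by = 0.05), function(ne) titration_delta(m, ne, 1, cfg))
    expect_true(all(diff(d) >= 0))
  }
  # sqrt floor keeps the step alive at a zero rate
  expect_gt(titration_delta(55, 0, 1, cfg), 0)
})

test_that("fluid responsiveness threshold is inclusive at +5 mmHg", {
  expect_identical(assess_responsiveness(52, 57, cfg), "responsive")
  expect_identical(assess_responsiveness(52, 56.9, cfg), "non_responsive")
  expect_identical(assess_responsiveness(52, 52, cfg), "non_responsive")
  expect_error(assess_responsiveness(NA_real_, 60, cfg))
})

test_that("responsiveness resets after four interventions or one hour", {
  st <- ctrl_state()
  st$responsiveness <- "responsive"
  st$last_test_time_s <- 1000

  s1 <- st; s1$interventions_since_test <- 4L
  expect_identical(maybe_reset_responsiveness(s1, 1600, cfg)$responsiveness, "unknown")

  s2 <- st; s2$interventions_since_test <- 2L
  expect_identical(maybe_reset_responsiveness(s2, 4600, cfg)$responsiveness, "unknown")

  s3 <- st; s3$interventions_since_test <- 3L
  out <- maybe_reset_responsiveness(s3, 1000 + 3599, cfg)
  expect_identical(out$responsiveness, "responsive")
  expect_identical(out$interventions_since_test, 3L)
})

mk_state <- function(ne_rate = 0.1, responsiveness = "unknown", ...) {
  st <- ctrl_state(ne_rate = ne_rate)
  st$responsiveness <- responsiveness
  extra <- list(...)
  st[names(extra)] <- extra
  st
}

test_that("severe hypotension fires a bolus and a simultaneous pressor increase", {
  d <- decide(vitals_window(1000, 45, 5), mk_state(ne_rate = 0.1), cfg)
  kinds <- vapply(d$interventions, `[[`, "", "kind")
  expect_setequal(kinds, c("fluid_bolus", "ne_increase"))
  expect_identical(unique(vapply(d$interventions, `[[`, "", "branch")),
                   "severe_hypotension")
  b <- d$interventions[[which(kinds == "fluid_bolus")]]
  expect_equal(b$magnitude, 5 * 70)   # 5 mL/kg x 70 kg = 350 mL
  expect_gt(d$state$ne_rate, 0.1)
  # counts once for the reset bookkeeping
  expect_identical(d$state$interventions_since_test, 1L)
})

test_that("normotension takes no action except the high-NE/low-CVP corner", {
  d <- decide(vitals_window(1000, 65, 8), mk_state(ne_rate = 0.1), cfg)
  expect_length(d$interventions, 0)
  expect_identical(d$zone, "normo")

  d2 <- decide(vitals_window(1000, 65, 5), mk_state(ne_rate = 0.6), cfg)
  expect_length(d2$interventions, 1)
  expect_identical(d2$interventions[[1]]$branch, "normotension_corner")
  expect_identical(d2$interventions[[1]]$kind, "fluid_bolus")

  # exhaustive grid over the quiet part of the normotensive region
  for (m in seq(60, 70, by = 1)) for (ne in c(0, 0.25, 0.5)) for (cvp in c(6, 9)) {
    d3 <- decide(vitals_window(0, m, cvp), mk_state(ne_rate = ne), cfg)
    expect_length(d3$interventions, 0)
  }
})

test_that("hypertension weans the pressor and stops at the floor", {
  d <- decide(vitals_window(1000, 75, 8), mk_state(ne_rate = 0.09), cfg)
  expect_identical(vapply(d$interventions, `[[`, "", "kind"), "ne_decrease")
  expect_equal(d$interventions[[1]]$magnitude, 0.0216)  # 0.0072*10*0.3
  expect_equal(d$state$ne_rate, 0.09 - 0.0216)

  d2 <- decide(vitals_window(1000, 72, 8), mk_state(ne_rate = 0), cfg)
  expect_length(d2$interventions, 0)   # nothing to wean at ne_min
})

test_that("moderate hypotension follows the responsiveness state machine", {
  # unknown -> test bolus, baseline recorded, counter zeroed
  d <- decide(vitals_window(1000, 55, 7), mk_state(responsiveness = "unknown"), cfg)
  expect_identical(d$interventions[[1]]$kind, "test_bolus")
  expect_equal(d$state$active_test$baseline_map, 55)
  expect_equal(d$state$last_test_time_s, 1000)
  expect_identical(d$state$interventions_since_test, 0L)

  # responsive -> fluid-avid
  d2 <- decide(vitals_window(1000, 55, 7), mk_state(responsiveness = "responsive"), cfg)
  expect_identical(d2$interventions[[1]]$kind, "fluid_bolus")
  expect_identical(d2$interventions[[1]]$branch, "moderate_hypotension_responsive")

  # non-responsive, CVP adequate -> pressor-avid
  d3 <- decide(vitals_window(1000, 55, 7), mk_state(responsiveness = "non_responsive"), cfg)
  expect_identical(d3$interventions[[1]]$kind, "ne_increase")

  # non-responsive, low CVP -> CVP-based fluid bolus instead
  d4 <- decide(vitals_window(1000, 55, 4), mk_state(responsiveness = "non_responsive"), cfg)
  expect_identical(d4$interventions[[1]]$kind, "fluid_bolus")
  expect_identical(d4$interventions[[1]]$branch, "cvp_based_fluid_bolus")

  # non-responsive, at maximum pressors -> pressor-resistance bolus
  d5 <- decide(vitals_window(1000, 55, 8),
               mk_state(ne_rate = 1.0, responsiveness = "non_responsive"), cfg)
  expect_identical(d5$interventions[[1]]$branch, "pressor_resistance")
  expect_identical(d5$interventions[[1]]$kind, "fluid_bolus")
})

test_that("a pending test bolus is assessed from the current window", {
  st <- mk_state(responsiveness = "unknown",
                 active_test = list(baseline_map = 52, start_s = 900))
  # +5 exactly at the boundary -> responsive; normotensive tick, no action
  d <- decide(vitals_window(1080, 62, 7), st, cfg)
  expect_identical(d$state$responsiveness, "responsive")
  expect_null(d$state$active_test)
  # below the boundary -> non-responsive
  st2 <- mk_state(responsiveness = "unknown",
                  active_test = list(baseline_map = 52, start_s = 900))
  d2 <- decide(vitals_window(1080, 56.9, 7), st2, cfg)
  expect_identical(d2$state$responsiveness, "non_responsive")
})

test_that("after four interventions the next moderate-hypotension tick retests", {
  st <- mk_state(responsiveness = "non_responsive",
                 last_test_time_s = 0, interventions_since_test = 0L)
  t <- 60
  for (i in 1:4) {
    d <- decide(vitals_window(t, 55, 8), st, cfg)  # pressor-avid increases
    expect_identical(d$interventions[[1]]$kind, "ne_increase")
    st <- d$state
    t <- t + 60
  }
  expect_identical(st$interventions_since_test, 4L)
  d <- decide(vitals_window(t, 55, 8), st, cfg)
  expect_identical(d$interventions[[1]]$kind, "test_bolus")
})

test_that("NE rate never leaves its bounds under fuzzed vitals streams", {
  set.seed(42)
  for (rep in 1:5) {
    st <- ctrl_state(ne_rate = runif(1, 0, 1))
    t <- 60
    for (i in 1:200) {
      w <- vitals_window(t, runif(1, 20, 110), runif(1, 0, 14))
      st <- decide(w, st, cfg)$state
      expect_gte(st$ne_rate, cfg$ne_min)
      expect_lte(st$ne_rate, cfg$ne_max)
      t <- t + 60
    }
  }
})

test_that("decisions are pure: identical inputs give identical outputs", {
  w <- vitals_window(123, 47.3, 4.2)
  st <- mk_state(ne_rate = 0.17, responsiveness = "non_responsive")
  expect_identical(decide(w, st, cfg), decide(w, st, cfg))
})

test_that("degenerate windows are rejected, not imputed", {
  expect_error(decide(vitals_window(100, NaN, 5), ctrl_state(), cfg), "invalid")
  expect_error(decide(vitals_window(100, 65, NA_real_), ctrl_state(), cfg), "invalid")
  expect_error(decide(vitals_window(30, 65, 5, warmup = TRUE), ctrl_state(), cfg),
               "warm-up")
})

test_that("configuration invariants are enforced", {
  expect_error(ctrl_config(weight_kg = -1))
  expect_error(ctrl_config(weight_kg = 70, map_severe = 65))
  expect_error(ctrl_config(weight_kg = 70, ne_min = 1, ne_max = 0.5))
  expect_error(ctrl_config(weight_kg = 70, bolus_dose = 0))
})
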