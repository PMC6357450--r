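# Outcome logic is exercised on hand-built trajectories (helper make_traj)
# so expected values follow directly from the definitions.

test_that("CR is the first assessable day at or below 5% with viable HSC", {
  courses <- list(therapy_course(10, 2, 1))
  days <- 10:40
  blast_drop <- c(0.25, rep(0.10, 7), rep(0.04, 23))   # <= 5% from day 18
  l <- blast_drop * 1e9
  tr <- make_traj(days, c1 = 1e9 - l, c2 = 1e9, l1 = l, l2 = 0,
                  courses = courses, diagnosis_day = 10, horizon = 40)
  expect_equal(detect_cr(tr), 18)

  # days within the course window are not assessable: blasts low on days
  # 11..17 must not count, first assessable day is start + 8
  l2 <- c(0.25, rep(0.01, 30)) * 1e9
  tr2 <- make_traj(days, c1 = 1e9 - l2, c2 = 1e9, l1 = l2, l2 = 0,
                   courses = courses, diagnosis_day = 10, horizon = 40)
  expect_equal(detect_cr(tr2), 18)

  # no HSC, no remission, even at zero blasts
  tr3 <- make_traj(days, c1 = rep(0, 31), c2 = 1e9,
                   l1 = rep(1e8, 31), l2 = 0,
                   courses = courses, diagnosis_day = 10, horizon = 40)
  expect_true(is.na(detect_cr(tr3)))

  # blasts never at or below 5%
  tr4 <- make_traj(days, c1 = 1e9, c2 = 1e9, l1 = rep(2e8, 31), l2 = 0,
                   courses = courses, diagnosis_day = 10, horizon = 40)
  expect_true(is.na(detect_cr(tr4)))
})

test_that("CR duration distinguishes relapse, depletion and censoring", {
  mk <- function(c1, blast) {
    l <- blast * (c1 + 1e9) / (1 - pmin(blast, 0.99))
    make_traj(seq_along(c1), c1 = c1, c2 = 1e9, l1 = l, l2 = 0,
              diagnosis_day = 1, horizon = length(c1))
  }
  # relapse the day after CR: duration 1
  tr <- mk(rep(1e9, 10), c(0.3, 0.3, 0.04, 0.06, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3))
  expect_equal(cr_duration(tr, 3), list(duration = 1, reason = "relapse"))

  # HSC depletion four days after CR
  tr <- mk(c(rep(1e9, 6), 0, 0, 0, 0), c(0.3, 0.3, rep(0.01, 8)))
  expect_equal(cr_duration(tr, 3), list(duration = 4,
                                        reason = "hsc_depletion"))

  # neither: censored at the horizon
  tr <- mk(rep(1e9, 10), c(0.3, 0.3, rep(0.01, 8)))
  expect_equal(cr_duration(tr, 3),
               list(duration = 7, reason = "censored_at_horizon"))
})

test_that("classification partitions into effective / over / under", {
  p <- fast_params()
  cfg <- sim_config(horizon = 600)
  # no therapy: leukemia persists, undertreatment
  expect_equal(classify_outcome(simulate_therapy(p, "standard", 0, 0, cfg)),
               "undertreatment")
  # extreme intensities wipe out every compartment: overtreatment
  tr <- simulate_therapy(p, "standard", 10, 10, cfg)
  expect_equal(classify_outcome(tr), "overtreatment")
  last <- tr[nrow(tr), ]
  expect_true(last$c1 == 0 && last$l1 == 0 && last$l2 == 0)
  # a working intensity reaches CR
  expect_equal(classify_outcome(simulate_therapy(p, "standard", 3, 0, cfg)),
               "effective")
})

test_that("day-29 cytoreduction is signed as a log10 reduction", {
  p <- fast_params()
  cfg <- sim_config(horizon = 300)
  # untreated leukemia grows: reduction is negative
  expect_lte(cytoreduction_day29(simulate_therapy(p, "standard", 0, 0, cfg)),
             0)
  # full eradication by day 29 is flagged as Inf
  expect_identical(cytoreduction_day29(
    simulate_therapy(p, "standard", 10, 10, cfg)), Inf)
  # direct check against the trajectory states
  tr <- simulate_therapy(p, "standard", 2.5, 0,
                         sim_config(horizon = 300, early_stop = FALSE))
  dx <- attr(tr, "diagnosis_day")
  want <- log10(sum(tr[tr$day == dx, c("l1", "l2")])) -
    log10(sum(tr[tr$day == dx + 29, c("l1", "l2")]))
  expect_equal(cytoreduction_day29(tr), want)
})

test_that("outcome records are internally consistent", {
  p <- fast_params()
  cfg <- sim_config(horizon = 600)
  for (k in list(c(0, 0), c(2.5, 0), c(0, 3), c(10, 10))) {
    oc <- extract_outcome(simulate_therapy(p, "standard", k[1], k[2], cfg))
    expect_identical(oc$classification == "effective", !is.na(oc$cr_day))
    if (!is.na(oc$cr_day)) {
      expect_equal(oc$time_to_cr, oc$cr_day - oc$diagnosis_day)
      expect_identical(oc$cr_class == "quasi_infinite",
                       oc$cr_end_reason == "censored_at_horizon")
      expect_gte(oc$time_to_cr, 8)
    }
  }
})

test_that("d2_l calibration recovers a known value (round trip)", {
  d2_true <- 0.08
  p <- aml_parameters(pace = "fast", d2_l = d2_true)
  anchor <- attr(run_untreated(p, 200, stop_at_diagnosis = TRUE),
                 "diagnosis_day")
  cal <- calibrate_d2l(anchor_day = anchor, bracket = c(0.02, 0.4))
  expect_gte(d2_true, cal$interval[1])
  expect_lte(d2_true, cal$interval[2])
  # the midpoint reproduces the anchor
  p2 <- aml_parameters(pace = "fast", d2_l = cal$d2_l)
  expect_equal(attr(run_untreated(p2, 200, stop_at_diagnosis = TRUE),
                    "diagnosis_day"), anchor)
})

test_that("calibration signals an unreachable anchor", {
  expect_error(calibrate_d2l(anchor_day = 40, bracket = c(0.02, 0.4),
                             config = sim_config(horizon = 300)),
               "no d2_l")
})

test_that("pace landscape: no leukemia without a self-renewal advantage", {
  grid <- pace_landscape(a_l = c(0.5, 0.8, 0.87, 1), p_l = c(0.42, 2),
                         d2_l = REF_D2L, horizon = 800)
  none <- grid$a_l <= 0.87
  expect_true(all(is.na(grid$diagnosis_day[none])))
  fast <- grid$a_l == 1 & grid$p_l == 2
  expect_equal(grid$diagnosis_day[fast],
               oracle_diagnosis_day(1, 2, REF_D2L))
})
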