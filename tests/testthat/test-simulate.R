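test_that("the healthy system stays at its steady state for 1000 days", {
  p <- fast_params()
  cfg <- sim_config(horizon = 1000, chunk_days = 1000)
  tr <- run_untreated(p, horizon = 1000, config = cfg,
                      init = initial_state(p, l1 = 0))
  expect_true(all(abs(tr$c1 / 2e9 - 1) < 1e-3))
  expect_true(all(abs(tr$c2 / 3.9e9 - 1) < 1e-3))
  expect_true(all(tr$l1 == 0 & tr$l2 == 0))
})

test_that("untreated diagnosis day matches the closed-form oracle", {
  # pre-diagnosis the leukemic subsystem is linear; the oracle solves it in
  # closed form (helper). Check several paces and clearance rates.
  cases <- expand.grid(a_l = c(1, 0.92), p_l = c(2, 1), d2_l = c(0.05, 0.15))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    p <- aml_parameters(a_l = cs$a_l, p_l = cs$p_l, d2_l = cs$d2_l)
    tr <- run_untreated(p, horizon = 2000, stop_at_diagnosis = TRUE)
    expect_equal(attr(tr, "diagnosis_day"),
                 oracle_diagnosis_day(cs$a_l, cs$p_l, cs$d2_l),
                 info = paste(cs, collapse = "/"))
  }
})

test_that("pre-diagnosis states match the closed form", {
  p <- fast_params()
  tr <- run_untreated(p, horizon = 60)
  oracle <- oracle_leukemic_load(tr$day, 1, 2, REF_D2L)
  expect_equal(tr$l1, oracle[, "l1"], tolerance = 1e-4)
  expect_equal(tr$l2, oracle[, "l2"], tolerance = 1e-4)
  expect_equal(tr$c1, rep(2e9, nrow(tr)), tolerance = 1e-6)
})

test_that("adaptive integrator agrees with a fixed-step RK4 reference", {
  # independent reference: classic 4th-order Runge-Kutta at fixed step 0.01
  # day, stepping day by day with the same daily extinction clamp
  p <- fast_params()
  tr <- run_untreated(p, horizon = 101,
                      config = sim_config(rtol = 1e-10, atol = 1e-8))
  y <- unname(initial_state(p))
  pv <- amlsim:::.rhs_parms(p, 0, 0)
  ref_daily <- matrix(NA_real_, nrow = 101, ncol = 4)
  ref_daily[1, ] <- y
  for (d in 1:100) {
    out <- deSolve::ode(y = y, times = seq(d, d + 1, by = 0.01),
                        func = amlsim:::.aml_rhs, parms = pv,
                        method = "rk4")
    y <- out[nrow(out), 2:5]
    y[y < p$extinction_threshold] <- 0
    ref_daily[d + 1, ] <- y
  }
  states <- as.matrix(as.data.frame(tr)[, c("c1", "c2", "l1", "l2")])
  rel <- abs(states - ref_daily) / pmax(abs(ref_daily), 1e-300)
  expect_lt(max(rel), 1e-4)
})

test_that("diagnosis day is robust to 10x tighter solver tolerances", {
  p <- fast_params()
  d1 <- attr(run_untreated(p, 200, sim_config(), stop_at_diagnosis = TRUE),
             "diagnosis_day")
  tight <- sim_config(rtol = 1e-9, atol = 1e-5)
  d2 <- attr(run_untreated(p, 200, tight, stop_at_diagnosis = TRUE),
             "diagnosis_day")
  expect_identical(d1, d2)
})

test_that("zero-intensity arms produce identical trajectories", {
  p <- fast_params()
  cfg <- sim_config(horizon = 300)
  t_std <- simulate_therapy(p, "standard", 0, 0, cfg)
  t_ev <- simulate_therapy(p, "evaluation", 0, 0, cfg)
  # the two arms segment the integration differently (evaluation-day
  # restarts), so agreement is at solver precision rather than bitwise
  expect_equal(as.data.frame(t_std)[, 1:8], as.data.frame(t_ev)[, 1:8],
               tolerance = 1e-6)
})

test_that("diagnosis triggers a schedule and therapy windows are honoured", {
  p <- fast_params()
  tr <- simulate_therapy(p, "standard", k_cyt = 3, k_anthra = 1.5)
  dx <- attr(tr, "diagnosis_day")
  expect_false(is.na(dx))
  courses <- attr(tr, "courses")
  expect_length(courses, 1)
  expect_equal(courses[[1]]$start_day, dx)
  d <- as.data.frame(tr)
  expect_true(all(d$k_cyt_active[d$day >= dx & d$day < dx + 7] == 3))
  expect_true(all(d$k_anthra_active[d$day >= dx & d$day < dx + 3] == 1.5))
  expect_true(all(d$k_cyt_active[d$day < dx | d$day >= dx + 7] == 0))
  expect_match(d$event[d$day == dx], "diagnosis")
})

test_that("once both leukemic compartments are extinct, blasts stay zero", {
  p <- fast_params()
  cfg <- sim_config(horizon = 2000, early_stop = FALSE, chunk_days = 1000)
  tr <- simulate_therapy(p, "standard", k_cyt = 4, k_anthra = 0, cfg)
  gone <- which(tr$l1 == 0 & tr$l2 == 0)
  expect_gt(length(gone), 0)
  after <- seq(min(gone), nrow(tr))
  expect_true(all(tr$l1[after] == 0 & tr$l2[after] == 0))
  expect_true(all(tr$blast[after] == 0, na.rm = TRUE))
})

test_that("early stopping does not change the extracted outcome", {
  p <- fast_params()
  for (k in c(2.5, 6)) {
    full <- simulate_therapy(p, "standard", k, 0,
                             sim_config(early_stop = FALSE))
    fast <- simulate_therapy(p, "standard", k, 0, sim_config())
    expect_lte(nrow(fast), nrow(full))
    expect_equal(extract_outcome(fast), extract_outcome(full))
  }
})

test_that("the evaluation arm re-induces on high day-14 blasts", {
  p <- fast_params()
  tr <- simulate_therapy(p, "evaluation", k_cyt = 2.5, k_anthra = 0)
  dx <- attr(tr, "diagnosis_day")
  courses <- attr(tr, "courses")
  expect_length(courses, 2)
  expect_equal(courses[[2]]$start_day, dx + 14)
  expect_equal(c(courses[[2]]$cyt_duration, courses[[2]]$anthra_duration),
               c(5, 2))
  expect_match(tr$event[tr$day == dx + 14], "evaluation")
})
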