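test_that("feedback signal matches its closed form and limits", {
  p <- fast_params()
  expect_equal(feedback_signal(c(c1 = 0, c2 = 0, l1 = 0, l2 = 0), p), 1)
  # at the healthy steady state s = 1 / (1 + 0.74) regardless of leukemia
  s_star <- 1 / (1 + p$k_c * 3.9e9)
  expect_equal(feedback_signal(c(c1 = 2e9, c2 = 3.9e9, l1 = 0, l2 = 0), p),
               s_star, tolerance = 1e-12)
  expect_equal(s_star, 1 / 1.74, tolerance = 1e-4)
  expect_lt(feedback_signal(c(0, 1e30, 0, 0), p), 1e-15)
})

test_that("feedback is decreasing in c2 and independent of the leukemic load", {
  p <- fast_params()
  c2 <- seq(0, 1e10, length.out = 50)
  s <- vapply(c2, function(v) feedback_signal(c(0, v, 0, 0), p), numeric(1))
  expect_true(all(diff(s) < 0))
  expect_identical(feedback_signal(c(1e9, 2e9, 0, 0), p),
                   feedback_signal(c(1e9, 2e9, 5e9, 7e9), p))
})

test_that("crowding death rate is zero below threshold, linear above", {
  p <- fast_params()
  expect_identical(crowding_death_rate(0, p), 0)
  expect_identical(crowding_death_rate(4e9, p), 0)
  expect_equal(crowding_death_rate(5e9, p), 0.1)     # 1e-10 * 1e9
  x <- seq(4e9, 1e10, length.out = 20)
  expect_equal(crowding_death_rate(x, p), 1e-10 * (x - 4e9))
})

test_that("blast fraction covers its boundary cases", {
  expect_equal(blast_fraction(c(c1 = 1e9, c2 = 0, l1 = 0, l2 = 0)), 0)
  expect_equal(blast_fraction(c(c1 = 0, c2 = 0, l1 = 1e8, l2 = 1e8)), 1)
  expect_equal(blast_fraction(c(c1 = 8e8, c2 = 0, l1 = 1e8, l2 = 1e8)), 0.2)
  # empty marrow: not evaluable
  expect_true(is.na(blast_fraction(c(c1 = 0, c2 = 5e8, l1 = 0, l2 = 0))))
  expect_true(is.na(blast_fraction(c(1e-3, 0, 1e-3, 1e-3))))
})

test_that("derivatives implement the printed system", {
  p <- fast_params()
  # steady state with no leukemia: all rates vanish
  expect_true(all(abs(aml_derivatives(initial_state(p, l1 = 0), p)) < 1e-6))

  # every term of the HSC equation is proportional to c1
  d <- aml_derivatives(c(c1 = 0, c2 = 1e9, l1 = 1e8, l2 = 1e8), p,
                       chemo = c(3, 2))
  expect_identical(unname(d["c1"]), 0)

  # small LSC load at the healthy steady state grows at (2 a_l s* - 1) p_l
  st <- initial_state(p, l1 = 1e4)
  s_star <- feedback_signal(st, p)
  d <- aml_derivatives(st, p)
  expect_equal(unname(d["l1"]), (2 * 1 * s_star * 2 - 2) * 1e4,
               tolerance = 1e-12)

  # chemotherapy asymmetries: cytarabine spares the non-proliferating
  # compartments, anthracycline hits them without the proliferation factor
  st <- c(c1 = 1e9, c2 = 2e9, l1 = 1e8, l2 = 3e8)
  d0 <- aml_derivatives(st, p)
  dc <- aml_derivatives(st, p, chemo = c(2, 0))
  da <- aml_derivatives(st, p, chemo = c(0, 2))
  expect_equal(unname(dc["c2"] - d0["c2"]), 0)
  expect_equal(unname(dc["l2"] - d0["l2"]), 0)
  expect_equal(unname(dc["c1"] - d0["c1"]), -2 * p$p_c * 1e9)
  expect_equal(unname(dc["l1"] - d0["l1"]), -2 * p$p_l * 1e8)
  expect_equal(unname(da["c2"] - d0["c2"]), -2 * 2e9)
  expect_equal(unname(da["l2"] - d0["l2"]), -2 * 3e8)

  expect_error(aml_derivatives(c(-1, 1, 1, 1), p), "non-negative")
})

test_that("non-negativity is forward-invariant on random boundary states", {
  p <- fast_params()
  set.seed(42)
  for (i in 1:250) {
    st <- stats::runif(4, 0, 1e10)
    zero <- sample(1:4, sample(1:3, 1))
    st[zero] <- 0
    d <- aml_derivatives(st, p, chemo = stats::runif(2, 0, 10))
    expect_true(all(d[zero] >= 0))
  }
})

test_that("zero-leukemia steady state is invadable iff a_l exceeds a_c", {
  # growth rate of a rare LSC clone at the healthy steady state:
  # (2 a_l s* - 1) p_l with s* = 1/(2 a_c); positive iff a_l > a_c
  for (a_l in c(0.5, 0.86, 0.87, 0.88, 1)) {
    p <- aml_parameters(a_l = a_l, p_l = 1.3, d2_l = REF_D2L)
    d <- aml_derivatives(initial_state(p, l1 = 1), p)
    if (a_l > 0.87) expect_gt(d[["l1"]], 0) else expect_lte(d[["l1"]], 0)
  }
})
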