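# Shared fixtures and independent oracles.

# A representative clearance rate for unit tests (acceptance tests calibrate
# their own value from the diagnosis-day anchor).
REF_D2L <- 0.1

fast_params <- function(d2_l = REF_D2L) aml_parameters(pace = "fast", d2_l = d2_l)

# Closed-form oracle for the untreated pre-diagnosis phase. While the blast
# fraction is below the diagnostic threshold the healthy compartments remain
# exactly at their steady state (the feedback depends only on c2, which is
# driven only by c1), so the leukemic subsystem is linear with constant
# coefficients and solves in closed form:
#   l1(t) = exp(lambda (t - 1)),  lambda = (2 a_l s* - 1) p_l, s* = 1/(2 a_c)
#   l2(t) = I / (lambda + d2_l) (exp(lambda(t-1)) - exp(-d2_l(t-1))),
#   I = (2 - 2 a_l s*) p_l
# with the single LSC seeded on day 1. Diagnosis is the first integer day
# with (l1 + l2) / (c1* + l1 + l2) >= 0.2, i.e. l1 + l2 >= c1* / 4.
oracle_leukemic_load <- function(t, a_l, p_l, d2_l, a_c = 0.87) {
  s_star <- 1 / (2 * a_c)
  lam <- (2 * a_l * s_star - 1) * p_l
  inflow <- (2 - 2 * a_l * s_star) * p_l
  u <- t - 1
  l1 <- exp(lam * u)
  l2 <- inflow / (lam + d2_l) * (exp(lam * u) - exp(-d2_l * u))
  cbind(l1 = l1, l2 = l2)
}

oracle_diagnosis_day <- function(a_l, p_l, d2_l, c1_star = 2e9,
                                 horizon = 6000) {
  load <- function(t) sum(oracle_leukemic_load(t, a_l, p_l, d2_l))
  if (load(horizon) < c1_star / 4) return(NA_integer_)
  cross <- stats::uniroot(function(t) load(t) - c1_star / 4,
                          c(1, horizon), tol = 1e-9)$root
  as.integer(ceiling(cross))
}

# Hand-built trajectory for outcome-logic tests (bypasses the integrator).
make_traj <- function(days, c1, c2, l1, l2, courses = list(),
                      diagnosis_day = days[1], horizon = max(days),
                      extinction_threshold = 1 / 70) {
  x <- c1 + l1 + l2
  blast <- ifelse(x < extinction_threshold, NA_real_, (l1 + l2) / x)
  df <- data.frame(day = days, c1 = c1, c2 = c2, l1 = l1, l2 = l2,
                   blast = blast, k_cyt_active = 0, k_anthra_active = 0,
                   event = "", stringsAsFactors = FALSE)
  structure(df, class = c("aml_trajectory", "data.frame"),
            params = NULL, policy = NULL, courses = courses,
            diagnosis_day = diagnosis_day, horizon = horizon,
            resolved = FALSE)
}
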