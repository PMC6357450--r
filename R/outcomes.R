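#' Days on which remission status can be assessed
#'
#' Remission is assessed on the daily grid but only once chemotherapy
#' courses are over: days inside any course window (from the course start
#' up to and including the end of its cytarabine window) are excluded, so
#' the earliest possible remission reading after a 7-day induction is 8
#' days after treatment start. This keeps the transient blast-fraction dips
#' that occur while drugs are still being infused from being scored as
#' remissions.
#'
#' @keywords internal
.assessable <- function(days, courses) {
  ok <- rep(TRUE, length(days))
  for (crs in courses)
    ok[days >= crs$start_day &
         days <= crs$start_day + crs$cyt_duration] <- FALSE
  ok
}

#' Detect complete remission
#'
#' Complete remission (CR) is a blast fraction of at most 5% with viable
#' hematopoiesis (HSC present). The CR day is the first assessable day
#' after diagnosis on which both hold; days within chemotherapy course
#' windows are not assessable (see the package vignette). A non-evaluable
#' blast fraction (empty marrow) never counts as remission.
#'
#' @param traj an `aml_trajectory` from [simulate_therapy()].
#' @param diagnosis_day defaults to the trajectory's recorded diagnosis.
#' @param threshold CR blast-fraction threshold.
#' @return The CR day, or `NA` if remission is never reached.
#' @export
detect_cr <- function(traj, diagnosis_day = attr(traj, "diagnosis_day"),
                      threshold = 0.05) {
  if (is.na(diagnosis_day)) return(NA_integer_)
  ok <- traj$day > diagnosis_day &
    .assessable(traj$day, attr(traj, "courses")) &
    !is.na(traj$blast) & traj$blast <= threshold & traj$c1 > 0
  i <- which(ok)
  if (length(i)) traj$day[i[1]] else NA_integer_
}

#' Duration of a complete remission
#'
#' Measures the time from CR to the first of: relapse (blast fraction above
#' 5%), depletion of all HSC (complete loss of normal hematopoiesis), or
#' the end of the simulation (censoring; a "quasi-infinite" remission in
#' this single-clone model, where the leukemic clone has been eradicated).
#'
#' @param traj an `aml_trajectory`.
#' @param cr_day day remission was reached (from [detect_cr()]).
#' @param horizon simulation horizon; defaults to the trajectory's.
#' @param threshold relapse blast-fraction threshold.
#' @return A list with `duration` (days) and `reason` (one of "relapse",
#'   "hsc_depletion", "censored_at_horizon").
#' @export
cr_duration <- function(traj, cr_day, horizon = attr(traj, "horizon"),
                        threshold = 0.05) {
  if (is.na(cr_day)) return(list(duration = NA_real_, reason = NA_character_))
  after <- traj$day > cr_day
  dep <- which(after & traj$c1 == 0)
  rel <- which(after & !is.na(traj$blast) & traj$blast > threshold)
  d_dep <- if (length(dep)) traj$day[dep[1]] else Inf
  d_rel <- if (length(rel)) traj$day[rel[1]] else Inf
  if (is.infinite(d_dep) && is.infinite(d_rel))
    return(list(duration = horizon - cr_day,
                reason = "censored_at_horizon"))
  if (d_dep <= d_rel)
    list(duration = d_dep - cr_day, reason = "hsc_depletion")
  else
    list(duration = d_rel - cr_day, reason = "relapse")
}

#' Classify the treatment outcome of one simulation
#'
#' A therapy-intensity combination is "effective" if a complete remission
#' is reached; otherwise it is "overtreatment" when intensive therapy has
#' completely depleted all marrow compartments (HSC, LSC and
#' non-proliferating leukemic cells all extinct) and "undertreatment" when
#' leukemic cells persist without remission.
#'
#' @param traj an `aml_trajectory`.
#' @param cr_day result of [detect_cr()]; recomputed if missing.
#' @return One of "effective", "overtreatment", "undertreatment".
#' @export
classify_outcome <- function(traj, cr_day = detect_cr(traj)) {
  if (!is.na(cr_day)) return("effective")
  last <- traj[nrow(traj), ]
  if (last$c1 == 0 && last$l1 == 0 && last$l2 == 0) "overtreatment"
  else "undertreatment"
}

#' Log10 cytoreduction 29 days after treatment start
#'
#' The order-of-magnitude reduction of the leukemic cell mass
#' (\eqn{l_1 + l_2}) between diagnosis and 29 days after treatment start —
#' the model analogue of the clinical "3 log10 cytoreduction" adequacy
#' criterion. Positive values are reductions; `Inf` flags complete
#' eradication of the leukemic compartments by day 29.
#'
#' @param traj an `aml_trajectory`.
#' @param diagnosis_day defaults to the trajectory's recorded diagnosis.
#' @return log10 reduction (dimensionless), `Inf` if extinct at day 29, or
#'   `NA` if day 29 lies beyond the horizon.
#' @export
cytoreduction_day29 <- function(traj,
                                diagnosis_day = attr(traj, "diagnosis_day")) {
  if (is.na(diagnosis_day)) return(NA_real_)
  day29 <- diagnosis_day + 29
  if (day29 > attr(traj, "horizon")) return(NA_real_)
  l_dx <- sum(traj[traj$day == diagnosis_day, c("l1", "l2")])
  i <- which(traj$day == day29)
  l_29 <- if (length(i)) sum(traj[i, c("l1", "l2")]) else {
    # trajectory stopped early: only happens once l1 = l2 = 0
    0
  }
  if (l_29 == 0) Inf else log10(l_dx) - log10(l_29)
}

#' Extract the clinical endpoints of one simulated patient
#'
#' @param traj an `aml_trajectory` from [simulate_therapy()].
#' @return A one-row data frame (an "outcome record") with columns
#'   `diagnosis_day`, `cr_day`, `time_to_cr`, `cr_duration`,
#'   `cr_end_reason`, `classification`, `cr_class` and
#'   `cytoreduction_log10_day29`. `cr_class` partitions remissions by how
#'   they end, which in this model coincides with the bimodal duration
#'   split: "quasi_infinite" (censored at the horizon — the leukemic clone
#'   was eradicated, so the remission persists), "short" (remission ended
#'   within days by regrowth of a residual clone, i.e. relapse) and "other"
#'   (remission ended by depletion of normal hematopoiesis).
#' @export
extract_outcome <- function(traj) {
  dx <- attr(traj, "diagnosis_day")
  cr <- detect_cr(traj)
  dur <- cr_duration(traj, cr)
  cls <- classify_outcome(traj, cr)
  cr_class <- if (is.na(cr)) NA_character_ else
    switch(dur$reason,
           censored_at_horizon = "quasi_infinite",
           relapse = "short",
           hsc_depletion = "other")
  data.frame(diagnosis_day = dx, cr_day = cr,
             time_to_cr = cr - dx,
             cr_duration = dur$duration,
             cr_end_reason = if (is.na(cr)) NA_character_ else dur$reason,
             classification = cls,
             cr_class = cr_class,
             cytoreduction_log10_day29 = cytoreduction_day29(traj),
             stringsAsFactors = FALSE)
}
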