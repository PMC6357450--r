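#' A single chemotherapy course
#'
#' A course is a pair of piecewise-constant therapy windows sharing a start
#' day: cytarabine-like therapy is active on
#' `[start_day, start_day + cyt_duration)` and anthracycline-like therapy
#' on `[start_day, start_day + anthra_duration)`. Induction uses 7 + 3
#' (7 days cytarabine, anthracycline on the first 3), re-induction the
#' intensity-reduced 5 + 2.
#'
#' @param start_day day the course starts.
#' @param k_cyt,k_anthra therapy intensities (1/day), fixed for the course.
#' @param cyt_duration,anthra_duration window lengths in days;
#'   `cyt_duration >= anthra_duration >= 0`.
#' @return An object of class `therapy_course`.
#' @examples
#' therapy_course(63, k_cyt = 2.5, k_anthra = 0)
#' @export
therapy_course <- function(start_day, k_cyt, k_anthra,
                           cyt_duration = 7, anthra_duration = 3) {
  if (anthra_duration < 0 || cyt_duration < anthra_duration)
    stop("need cyt_duration >= anthra_duration >= 0", call. = FALSE)
  if (k_cyt < 0 || k_anthra < 0)
    stop("therapy intensities must be non-negative", call. = FALSE)
  structure(list(start_day = start_day, k_cyt = k_cyt, k_anthra = k_anthra,
                 cyt_duration = cyt_duration,
                 anthra_duration = anthra_duration),
            class = "therapy_course")
}

#' @export
print.therapy_course <- function(x, ...) {
  cat(sprintf("%d + %d course @ day %g: k_cyt = %g, k_anthra = %g\n",
              x$cyt_duration, x$anthra_duration, x$start_day,
              x$k_cyt, x$k_anthra))
  invisible(x)
}

#' Active chemotherapy intensities at a time point
#'
#' Resolves a list of non-overlapping [therapy_course()]s to the
#' intensities active at time `t`: `k_cyt` within the cytarabine window,
#' `k_anthra` within the anthracycline window, zero outside.
#'
#' @param t time in days.
#' @param courses list of [therapy_course()] objects; their cytarabine
#'   windows must not intersect.
#' @return Named numeric vector `c(k_cyt = , k_anthra = )`.
#' @examples
#' crs <- list(therapy_course(63, 2, 1))
#' chemo_at_time(64.5, crs)  # both active
#' chemo_at_time(68, crs)    # anthracycline window over
#' @export
chemo_at_time <- function(t, courses) {
  .check_course_overlap(courses)
  k_cyt <- 0
  k_anthra <- 0
  for (crs in courses) {
    if (t >= crs$start_day && t < crs$start_day + crs$cyt_duration)
      k_cyt <- k_cyt + crs$k_cyt
    if (t >= crs$start_day && t < crs$start_day + crs$anthra_duration)
      k_anthra <- k_anthra + crs$k_anthra
  }
  c(k_cyt = k_cyt, k_anthra = k_anthra)
}

.check_course_overlap <- function(courses) {
  if (length(courses) < 2) return(invisible(TRUE))
  win <- t(vapply(courses, function(crs)
    c(crs$start_day, crs$start_day + crs$cyt_duration), numeric(2)))
  win <- win[order(win[, 1]), , drop = FALSE]
  if (any(win[-1, 1] < win[-nrow(win), 2]))
    stop("therapy courses overlap in time", call. = FALSE)
  invisible(TRUE)
}

#' Regimen policy: study arm and bone-marrow evaluation rules
#'
#' The standard arm gives a single 7 + 3 induction at diagnosis. The
#' evaluation arm adds bone-marrow evaluations 14 and 21 days after
#' treatment start: a blast fraction of at least 5.5% on day 14, or —
#' failing that trigger — at least 5% on day 21, leads to one
#' intensity-reduced 5 + 2 re-induction at the same preset intensities.
#'
#' @param arm "standard" or "evaluation".
#' @param eval_days days after treatment start of the first and second
#'   bone-marrow evaluation.
#' @param eval_thresholds blast-fraction triggers (inclusive `>=`) for the
#'   two evaluations.
#' @param induction durations (cytarabine, anthracycline) of the first
#'   course.
#' @param reinduction durations of the conditional second course.
#' @return An object of class `regimen_policy`.
#' @examples
#' regimen_policy("evaluation")
#' @export
regimen_policy <- function(arm = c("standard", "evaluation"),
                           eval_days = c(14, 21),
                           eval_thresholds = c(0.055, 0.05),
                           induction = c(7, 3),
                           reinduction = c(5, 2)) {
  arm <- match.arg(arm)
  if (length(eval_days) != 2 || eval_days[1] >= eval_days[2])
    stop("eval_days must be two increasing day offsets", call. = FALSE)
  if (any(eval_thresholds <= 0) || any(eval_thresholds >= 1))
    stop("evaluation thresholds must lie in (0, 1)", call. = FALSE)
  structure(list(arm = arm, eval_days = eval_days,
                 eval_thresholds = eval_thresholds,
                 induction = induction, reinduction = reinduction),
            class = "regimen_policy")
}

#' @export
print.regimen_policy <- function(x, ...) {
  cat(sprintf("%s arm: %d+%d induction", x$arm,
              x$induction[1], x$induction[2]))
  if (x$arm == "evaluation")
    cat(sprintf("; BM evaluation day %d (>= %.3g) / day %d (>= %.3g) -> %d+%d",
                x$eval_days[1], x$eval_thresholds[1],
                x$eval_days[2], x$eval_thresholds[2],
                x$reinduction[1], x$reinduction[2]))
  cat("\n")
  invisible(x)
}

#' Named regimen presets
#'
#' @param name "standard_7p3" (single induction) or "evaluation_7p3"
#'   (induction plus conditional 5 + 2 re-induction).
#' @return A [regimen_policy()] object.
#' @export
regimen_preset <- function(name = c("standard_7p3", "evaluation_7p3")) {
  name <- match.arg(name)
  regimen_policy(if (name == "standard_7p3") "standard" else "evaluation")
}

#' Bone-marrow evaluation decision
#'
#' Implements the adaptive rule of the evaluation arm. The day-14 reading
#' triggers re-induction when at least 5.5% blasts; only when it is below
#' that threshold is the day-21 reading consulted, where at least 5%
#' triggers re-induction. Comparisons are inclusive and blast values are
#' not rounded. A non-evaluable reading (`NA`, empty marrow) never triggers
#' re-induction of a depleted system.
#'
#' @param blast_day14 blast fraction at the first evaluation (or `NA`).
#' @param blast_day21 blast fraction at the second evaluation (or `NA` /
#'   `NULL` if not taken).
#' @param policy a [regimen_policy()].
#' @return One of "re_induce_at_14", "re_induce_at_21", "observe".
#' @examples
#' evaluation_decision(0.06, policy = regimen_policy("evaluation"))
#' evaluation_decision(0.054, 0.050, regimen_policy("evaluation"))
#' @export
evaluation_decision <- function(blast_day14, blast_day21 = NULL,
                                policy = regimen_policy("evaluation")) {
  thr <- policy$eval_thresholds
  if (!is.na(blast_day14) && blast_day14 >= thr[1])
    return("re_induce_at_14")
  if (!is.null(blast_day21) && !is.na(blast_day21) && blast_day21 >= thr[2])
    return("re_induce_at_21")
  "observe"
}

#' Build the therapy schedule for one simulated patient
#'
#' Realises the regimen policy as a list of [therapy_course()]s given the
#' diagnosis day and a way to read the blast fraction on the evaluation
#' days. The standard arm yields exactly one 7 + 3 course starting on the
#' diagnosis day (treatment starts immediately); the evaluation arm adds at
#' most one 5 + 2 course starting on the triggering evaluation day, at the
#' same preset intensities.
#'
#' @param policy a [regimen_policy()].
#' @param diagnosis_day day the blast fraction first reached the 20%
#'   diagnostic threshold.
#' @param k_cyt,k_anthra preset intensities used for all courses.
#' @param blast_lookup function mapping a day to the blast fraction of the
#'   trajectory under this schedule (used only by the evaluation arm).
#' @return List of [therapy_course()] objects.
#' @examples
#' pol <- regimen_policy("evaluation")
#' build_schedule(pol, 63, 2, 1, function(day) 0.40)
#' @export
build_schedule <- function(policy, diagnosis_day, k_cyt, k_anthra,
                           blast_lookup = NULL) {
  first <- therapy_course(diagnosis_day, k_cyt, k_anthra,
                          policy$induction[1], policy$induction[2])
  courses <- list(first)
  if (policy$arm == "evaluation") {
    if (is.null(blast_lookup))
      stop("the evaluation arm needs a blast_lookup", call. = FALSE)
    d14 <- diagnosis_day + policy$eval_days[1]
    b14 <- blast_lookup(d14)
    decision <- evaluation_decision(b14, NULL, policy)
    if (decision == "observe") {
      d21 <- diagnosis_day + policy$eval_days[2]
      decision <- evaluation_decision(b14, blast_lookup(d21), policy)
    }
    start2 <- switch(decision,
                     re_induce_at_14 = d14,
                     re_induce_at_21 = diagnosis_day + policy$eval_days[2],
                     NULL)
    if (!is.null(start2))
      courses <- c(courses, list(
        therapy_course(start2, k_cyt, k_anthra,
                       policy$reinduction[1], policy$reinduction[2])))
  }
  courses
}
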