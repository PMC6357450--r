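#' Simulation configuration
#'
#' Controls the numerical integration and output of the simulation engine.
#' The system is integrated with a stiff-capable solver with automatic
#' method switching (deSolve's `lsoda`), restarted at every therapy on/off
#' switch so discontinuities never cross an integrator step, with states
#' reported on a daily grid. After each daily step any compartment below
#' the extinction threshold (one cell in the patient, 1/70 cells/kg) is
#' clamped to zero.
#'
#' @param horizon last simulated day; days are counted 1-based, the single
#'   leukemic cell is seeded on day 1. 2000 by default (use 5000 for the
#'   slow pace).
#' @param rtol,atol relative and absolute integrator tolerances. `atol` is
#'   well below the extinction threshold so near-extinct compartments are
#'   still resolved.
#' @param chunk_days length of integration segments outside therapy
#'   switches.
#' @param early_stop stop integrating once the remaining course of the
#'   trajectory is determined (leukemic compartments extinct after the end
#'   of therapy and after the day-29 cytoreduction reading); all clinical
#'   endpoints are unaffected.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(horizon = 2000, rtol = 1e-8, atol = 1e-4,
                       chunk_days = 256, early_stop = TRUE) {
  if (horizon < 1) stop("horizon must be at least 1 day", call. = FALSE)
  structure(list(horizon = horizon, rtol = rtol, atol = atol,
                 chunk_days = chunk_days, early_stop = early_stop),
            class = "sim_config")
}

# integrate one segment on the daily grid [t0, t1] with constant chemo,
# clamping sub-extinction compartments at every day boundary. Returns the
# (t1 - t0 + 1) x 4 state matrix including the row at t0.
.integrate_days <- function(y, t0, t1, pv, thr, config) {
  times <- seq(t0, t1)
  clamp <- function(t, y, p) { y[y < thr] <- 0; y }
  out <- deSolve::ode(y = unname(y), times = times, func = .aml_rhs,
                      parms = pv, events = list(func = clamp, time = times),
                      rtol = config$rtol, atol = config$atol)
  if (attr(out, "istate")[1] < 0)
    stop("ODE solver failed (step size below minimum); ",
         "check parameters and tolerances", call. = FALSE)
  st <- unname(out[, 2:5, drop = FALSE])
  # rows are reported before the day's clamp is applied; re-apply so the
  # stored daily states are the ones the integration continued from
  st[st < thr] <- 0
  st
}

.blast_of_rows <- function(st, thr) {
  x <- st[, 1] + st[, 3] + st[, 4]
  b <- (st[, 3] + st[, 4]) / x
  b[x < thr] <- NA_real_
  b
}

# run from day `start_day` until the blast fraction first reaches
# `threshold` on the daily grid (or until leukemic extinction / horizon).
.presimulate <- function(params, config, init, threshold = 0.2,
                         start_day = 1) {
  pv <- .rhs_parms(params, 0, 0)
  thr <- params$extinction_threshold
  y <- .state_vec(init)
  days <- start_day
  states <- matrix(y, nrow = 1)
  t0 <- start_day
  diagnosis_day <- NA_integer_
  repeat {
    if (t0 >= config$horizon) break
    t1 <- min(t0 + config$chunk_days, config$horizon)
    st <- .integrate_days(y, t0, t1, pv, thr, config)
    b <- .blast_of_rows(st, thr)
    hit <- which(!is.na(b) & b >= threshold)
    keep <- if (length(hit)) hit[1] else nrow(st)
    states <- rbind(states, st[-1, , drop = FALSE][seq_len(keep - 1), ,
                                                   drop = FALSE])
    days <- c(days, seq(t0 + 1, t0 + keep - 1))
    if (length(hit)) {
      diagnosis_day <- t0 + hit[1] - 1
      break
    }
    y <- st[nrow(st), ]
    if (y[3] == 0 && y[4] == 0) break   # leukemia extinct, no diagnosis ever
    t0 <- t1
  }
  list(days = days, states = states, diagnosis_day = diagnosis_day,
       state_at_diagnosis = if (!is.na(diagnosis_day))
         states[nrow(states), ] else NULL)
}

.new_trajectory <- function(days, states, blast, k_cyt_active,
                            k_anthra_active, event, params, policy, courses,
                            diagnosis_day, config, resolved) {
  df <- data.frame(day = days, c1 = states[, 1], c2 = states[, 2],
                   l1 = states[, 3], l2 = states[, 4], blast = blast,
                   k_cyt_active = k_cyt_active,
                   k_anthra_active = k_anthra_active,
                   event = event, stringsAsFactors = FALSE)
  structure(df, class = c("aml_trajectory", "data.frame"),
            params = params, policy = policy, courses = courses,
            diagnosis_day = diagnosis_day, horizon = config$horizon,
            resolved = resolved)
}

#' Simulate one leukemia under a treatment regimen
#'
#' Runs the full in-silico patient: the system starts in the healthy steady
#' state with one leukemic stem cell per kg on day 1 and is integrated day
#' by day. When the marrow blast fraction first reaches 20% (diagnosis),
#' treatment starts immediately: a 7 + 3 course in both arms, and in the
#' evaluation arm bone-marrow evaluations on days 14/21 after treatment
#' start that may trigger one 5 + 2 re-induction (see [regimen_policy()]).
#' Integration is restarted at every therapy switch; compartments below the
#' extinction threshold are set to zero after every daily step.
#'
#' @param params an [aml_parameters()] object (with `d2_l` set).
#' @param policy a [regimen_policy()] object, or "standard"/"evaluation".
#' @param k_cyt,k_anthra preset therapy intensities (1/day).
#' @param config a [sim_config()].
#' @param init initial state; defaults to the healthy steady state plus one
#'   LSC per kg.
#' @param presim optional result of a previous pre-diagnosis run with the
#'   same parameters (used by [sweep_intensities()] to share the identical
#'   pre-treatment phase across grid cells); the returned trajectory then
#'   starts at the diagnosis day.
#' @return An `aml_trajectory`: a data frame with one row per day (columns
#'   `day`, `c1`, `c2`, `l1`, `l2`, `blast`, `k_cyt_active`,
#'   `k_anthra_active`, `event`) carrying the schedule, diagnosis day and
#'   horizon as attributes. If `early_stop` is set the trajectory may end
#'   before the horizon once its continuation is fully determined (leukemic
#'   compartments extinct after end of therapy).
#' @examples
#' \donttest{
#' p <- aml_parameters(pace = "fast", d2_l = 0.113)
#' traj <- simulate_therapy(p, "standard", k_cyt = 3, k_anthra = 0)
#' extract_outcome(traj)
#' }
#' @export
simulate_therapy <- function(params, policy = "standard", k_cyt, k_anthra,
                             config = sim_config(), init = initial_state(params),
                             presim = NULL) {
  if (is.character(policy)) policy <- regimen_policy(policy)
  thr <- params$extinction_threshold
  if (is.null(presim)) presim <- .presimulate(params, config, init)
  dx <- presim$diagnosis_day

  if (is.na(dx)) {               # never diagnosed within the horizon
    st <- presim$states
    b <- .blast_of_rows(st, thr)
    n <- length(presim$days)
    return(.new_trajectory(presim$days, st, b, numeric(n), numeric(n),
                           character(n), params, policy, list(),
                           NA_integer_, config,
                           resolved = presim$days[n] < config$horizon))
  }

  days <- presim$days
  states <- presim$states
  events <- character(length(days))
  events[length(events)] <- "diagnosis"

  courses <- list(therapy_course(dx, k_cyt, k_anthra,
                                 policy$induction[1], policy$induction[2]))
  # breakpoints where the active intensities change or decisions are taken
  run_segment <- function(t1, kc, ka) {
    if (t1 <= days[length(days)]) return(invisible(NULL))
    t0 <- days[length(days)]
    pv <- .rhs_parms(params, kc, ka)
    st <- .integrate_days(states[nrow(states), ], t0, t1, pv, thr, config)
    states <<- rbind(states, st[-1, , drop = FALSE])
    days <<- c(days, seq(t0 + 1, t1))
    events <<- c(events, character(t1 - t0))
    invisible(NULL)
  }
  mark <- function(day, label) {
    i <- match(day, days)
    if (!is.na(i))
      events[i] <<- if (nzchar(events[i])) paste(events[i], label, sep = ";")
        else label
  }
  play_course <- function(crs) {
    mark(crs$start_day, "course_start")
    end_anthra <- min(crs$start_day + crs$anthra_duration, config$horizon)
    end_cyt <- min(crs$start_day + crs$cyt_duration, config$horizon)
    run_segment(end_anthra, crs$k_cyt, crs$k_anthra)
    run_segment(end_cyt, crs$k_cyt, 0)
  }

  play_course(courses[[1]])
  if (policy$arm == "evaluation") {
    second_start <- NULL
    d14 <- dx + policy$eval_days[1]
    if (d14 <= config$horizon) {
      run_segment(d14, 0, 0)
      mark(d14, "evaluation")
      b14 <- blast_fraction(states[nrow(states), ], thr)
      if (evaluation_decision(b14, NULL, policy) == "re_induce_at_14") {
        second_start <- d14
      } else {
        d21 <- dx + policy$eval_days[2]
        if (d21 <= config$horizon) {
          run_segment(d21, 0, 0)
          mark(d21, "evaluation")
          b21 <- blast_fraction(states[nrow(states), ], thr)
          if (evaluation_decision(b14, b21, policy) == "re_induce_at_21")
            second_start <- d21
        }
      }
    }
    if (!is.null(second_start)) {
      crs2 <- therapy_course(second_start, k_cyt, k_anthra,
                             policy$reinduction[1], policy$reinduction[2])
      courses <- c(courses, list(crs2))
      play_course(crs2)
    }
  }

  # observation until the horizon, stopping early once nothing can change:
  # leukemic compartments extinct (no relapse possible, healthy recovery or
  # aplasia fully determined) and the day-29 cytoreduction reading passed
  resolved <- FALSE
  repeat {
    tcur <- days[length(days)]
    if (tcur >= config$horizon) break
    last <- states[nrow(states), ]
    if (config$early_stop && tcur >= dx + 29 &&
        last[3] == 0 && last[4] == 0) {
      resolved <- TRUE
      break
    }
    run_segment(min(tcur + config$chunk_days, config$horizon), 0, 0)
  }

  b <- .blast_of_rows(states, thr)
  kc_active <- numeric(length(days))
  ka_active <- numeric(length(days))
  for (crs in courses) {
    kc_active[days >= crs$start_day &
                days < crs$start_day + crs$cyt_duration] <- crs$k_cyt
    ka_active[days >= crs$start_day &
                days < crs$start_day + crs$anthra_duration] <- crs$k_anthra
  }
  .new_trajectory(days, states, b, kc_active, ka_active, events, params,
                  policy, courses, dx, config, resolved)
}

#' Simulate the untreated course of a leukemia
#'
#' Integrates the system without any therapy, e.g. to measure the leukemic
#' pace (time from one seeded LSC to the 20% diagnostic threshold).
#'
#' @param params an [aml_parameters()] object.
#' @param horizon last simulated day.
#' @param config a [sim_config()]; its horizon is overridden by `horizon`.
#' @param init initial state.
#' @param stop_at_diagnosis if `TRUE`, stop at the first day the blast
#'   fraction reaches 20% (the run always stops early if the leukemic
#'   compartments go extinct).
#' @return An `aml_trajectory` (therapy columns all zero).
#' @examples
#' \donttest{
#' p <- aml_parameters(pace = "fast", d2_l = 0.113)
#' tr <- run_untreated(p, horizon = 100, stop_at_diagnosis = TRUE)
#' attr(tr, "diagnosis_day")
#' }
#' @export
run_untreated <- function(params, horizon = 2000, config = sim_config(),
                          init = initial_state(params),
                          stop_at_diagnosis = FALSE) {
  config$horizon <- horizon
  thr <- params$extinction_threshold
  pre <- .presimulate(params, config, init,
                      threshold = if (stop_at_diagnosis) 0.2 else Inf)
  dx <- pre$diagnosis_day
  days <- pre$days
  states <- pre$states
  if (!stop_at_diagnosis || is.na(dx)) {
    b <- .blast_of_rows(states, thr)
    diagnosed <- which(!is.na(b) & b >= 0.2)
    dx <- if (length(diagnosed)) days[diagnosed[1]] else NA_integer_
  }
  b <- .blast_of_rows(states, thr)
  n <- length(days)
  events <- character(n)
  if (!is.na(dx)) events[match(dx, days)] <- "diagnosis"
  .new_trajectory(days, states, b, numeric(n), numeric(n), events, params,
                  NULL, list(), dx, config,
                  resolved = days[n] < config$horizon && is.na(dx))
}

#' @export
print.aml_trajectory <- function(x, ...) {
  dx <- attr(x, "diagnosis_day")
  cat(sprintf("AML trajectory: days %g..%g (horizon %g)\n",
              x$day[1], x$day[nrow(x)], attr(x, "horizon")))
  cat(if (is.na(dx)) "  no diagnosis reached\n" else
    sprintf("  diagnosis (20%% blasts) on day %d\n", dx))
  for (crs in attr(x, "courses"))
    cat("  ", format(crs$cyt_duration), "+", format(crs$anthra_duration),
        "course @ day", crs$start_day, "\n")
  if (isTRUE(attr(x, "resolved")))
    cat("  stopped early: remaining course fully determined\n")
  invisible(x)
}

#' Write a trajectory to a tab-separated file
#'
#' @param traj an `aml_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
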