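#' Derive the feedback coefficient and healthy clearance rate from the
#' healthy steady state
#'
#' The healthy two-compartment system admits a positive steady state
#' \eqn{(c_1^*, c_2^*)} only when the stem-cell self-renewal fraction
#' exceeds 1/2. Setting the stem-cell and differentiated-cell balance
#' equations to zero at \eqn{(c_1^*, c_2^*)} (no leukemic cells, no therapy,
#' no crowding) yields closed forms for the feedback coefficient and the
#' clearance rate of differentiated cells:
#' \deqn{k_c = (2 a_c - 1) / c_2^*, \qquad d_2^c = p_c c_1^* / c_2^*.}
#'
#' @param a_c healthy self-renewal fraction (must exceed 0.5 for a positive
#'   steady state).
#' @param p_c healthy proliferation rate (1/day).
#' @param c1_star steady-state hematopoietic stem cell abundance (cells/kg);
#'   must not exceed the crowding threshold so that the crowding death rate
#'   vanishes at steady state.
#' @param c2_star steady-state differentiated healthy cell abundance
#'   (cells/kg).
#'
#' @return A list with components `k_c` (feedback coefficient, kg/cells) and
#'   `d2_c` (clearance rate of differentiated healthy cells, 1/day).
#'
#' @examples
#' derive_steady_parameters(0.87, 0.42, 2e9, 3.9e9)
#' @export
derive_steady_parameters <- function(a_c, p_c, c1_star, c2_star) {
  stopifnot(is.numeric(a_c), is.numeric(p_c), is.numeric(c1_star),
            is.numeric(c2_star))
  if (any(c(p_c, c1_star, c2_star) <= 0))
    stop("p_c, c1_star and c2_star must be positive", call. = FALSE)
  if (a_c <= 0.5)
    stop("infeasible steady-state closure: a_c must exceed 0.5 ",
         "(no positive steady state otherwise)", call. = FALSE)
  list(k_c = (2 * a_c - 1) / c2_star,
       d2_c = p_c * c1_star / c2_star)
}

#' Leukemia pace presets
#'
#' Named leukemic parameter combinations characterised by their time from a
#' single seeded leukemic stem cell to the 20% diagnostic blast threshold:
#' "fast" (self-renewal 1, proliferation 2/day), "intermediate" (0.92, 1)
#' and "slow" (0.9, 0.2). The "healthy" entry returns the healthy
#' hematopoietic parametrisation (0.87, 0.42) for reference.
#'
#' @param pace one of "fast", "intermediate", "slow", "healthy".
#' @return A list with `a_l`, `p_l` and `default_horizon` (days; 5000 for
#'   the slow pace, 2000 otherwise).
#' @examples
#' pace_preset("fast")
#' @export
pace_preset <- function(pace = c("fast", "intermediate", "slow", "healthy")) {
  pace <- match.arg(pace)
  switch(pace,
         fast         = list(a_l = 1,    p_l = 2,    default_horizon = 2000),
         intermediate = list(a_l = 0.92, p_l = 1,    default_horizon = 2000),
         slow         = list(a_l = 0.9,  p_l = 0.2,  default_horizon = 5000),
         healthy      = list(a_l = 0.87, p_l = 0.42, default_horizon = 2000))
}

#' Model parameters for the coupled healthy/leukemic hematopoiesis system
#'
#' Assembles the full rate-constant set of the two-compartment
#' healthy/leukemic model. The feedback coefficient `k_c` and the healthy
#' clearance rate `d2_c` are derived from the healthy steady state via
#' [derive_steady_parameters()] so that the system starts stationary in the
#' absence of leukemic cells. The clearance rate of non-proliferating
#' leukemic cells, `d2_l`, has no published value and must be supplied
#' explicitly — typically from [calibrate_d2l()], which pins it to the
#' fast-pace diagnosis day.
#'
#' @param a_l leukemic self-renewal fraction in \[0, 1\], or use `pace`.
#' @param p_l leukemic proliferation rate in \[0, 2\] (1/day), or use `pace`.
#' @param d2_l clearance rate of non-proliferating leukemic cells (1/day);
#'   required, no default.
#' @param pace optional preset name (see [pace_preset()]) supplying
#'   `a_l`/`p_l`.
#' @param a_c,p_c healthy self-renewal fraction and proliferation rate.
#' @param c1_star,c2_star healthy steady state used for the parameter
#'   closure (cells/kg).
#' @param crowding_coeff slope of the marrow-crowding death rate
#'   (kg/cells/day).
#' @param crowding_threshold marrow cellularity above which crowding death
#'   sets in (cells/kg).
#' @param extinction_threshold abundance below which a compartment is
#'   treated as extinct: one cell in a 70 kg patient, 1/70 cells/kg.
#'
#' @return An object of class `aml_parameters`: a named list with all rate
#'   constants including the derived `k_c` and `d2_c`.
#'
#' @examples
#' aml_parameters(pace = "fast", d2_l = 0.1)
#' @export
aml_parameters <- function(a_l = NULL, p_l = NULL, d2_l, pace = NULL,
                           a_c = 0.87, p_c = 0.42,
                           c1_star = 2e9, c2_star = 3.9e9,
                           crowding_coeff = 1e-10,
                           crowding_threshold = 4e9,
                           extinction_threshold = 1 / 70) {
  if (!is.null(pace)) {
    preset <- pace_preset(pace)
    if (is.null(a_l)) a_l <- preset$a_l
    if (is.null(p_l)) p_l <- preset$p_l
  }
  if (is.null(a_l) || is.null(p_l))
    stop("supply either a pace preset or both a_l and p_l", call. = FALSE)
  if (missing(d2_l) || is.null(d2_l))
    stop("d2_l is required and has no default; calibrate it with ",
         "calibrate_d2l()", call. = FALSE)
  if (a_l < 0 || a_l > 1 || a_c < 0 || a_c > 1)
    stop("self-renewal fractions must lie in [0, 1]", call. = FALSE)
  if (p_l < 0 || p_l > 2 || p_c < 0 || p_c > 2)
    stop("proliferation rates must lie in [0, 2] per day", call. = FALSE)
  if (d2_l < 0) stop("d2_l must be non-negative", call. = FALSE)
  if (c1_star > crowding_threshold)
    stop("c1_star must not exceed the crowding threshold", call. = FALSE)
  closure <- derive_steady_parameters(a_c, p_c, c1_star, c2_star)
  structure(list(a_c = a_c, p_c = p_c, a_l = a_l, p_l = p_l,
                 d2_c = closure$d2_c, d2_l = d2_l, k_c = closure$k_c,
                 c1_star = c1_star, c2_star = c2_star,
                 crowding_coeff = crowding_coeff,
                 crowding_threshold = crowding_threshold,
                 extinction_threshold = extinction_threshold),
            class = "aml_parameters")
}

#' @export
print.aml_parameters <- function(x, ...) {
  cat("Hematopoiesis/AML model parameters\n")
  cat(sprintf("  healthy:  a_c = %.3g, p_c = %.3g/day, d2_c = %.5g/day\n",
              x$a_c, x$p_c, x$d2_c))
  cat(sprintf("  leukemic: a_l = %.3g, p_l = %.3g/day, d2_l = %.5g/day\n",
              x$a_l, x$p_l, x$d2_l))
  cat(sprintf("  feedback: k_c = %.5g kg/cells (steady state %.3g / %.3g cells/kg)\n",
              x$k_c, x$c1_star, x$c2_star))
  cat(sprintf("  crowding above %.3g cells/kg; extinction below %.4g cells/kg\n",
              x$crowding_threshold, x$extinction_threshold))
  invisible(x)
}

#' Default initial state: healthy steady state plus one seeded LSC
#'
#' All simulations start in the steady state of the healthy system with a
#' single leukemic stem cell per kg seeded into the LSC compartment on
#' day 1.
#'
#' @param params an [aml_parameters()] object.
#' @param l1 initial leukemic stem cell abundance (cells/kg); 0 gives the
#'   pure healthy system.
#' @return Named numeric state vector `c(c1, c2, l1, l2)`.
#' @export
initial_state <- function(params, l1 = 1) {
  c(c1 = params$c1_star, c2 = params$c2_star, l1 = l1, l2 = 0)
}
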