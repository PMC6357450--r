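#' Feedback signal regulating self-renewal
#'
#' Cellular communication (G-CSF-like feedback) is modelled as a signal
#' \eqn{s = 1 / (1 + k_c c_2)} that decreases with the abundance of
#' differentiated healthy cells and multiplies the self-renewal terms of
#' both healthy and leukemic stem cells. The signal depends only on the
#' healthy differentiated compartment: leukemic cells do not down-regulate
#' it (no negative feedback by the leukemic bulk).
#'
#' @param state named numeric state vector with at least a `c2` component,
#'   or a plain numeric vector `c(c1, c2, l1, l2)`.
#' @param params an [aml_parameters()] object.
#' @return Dimensionless signal in (0, 1].
#' @examples
#' p <- aml_parameters(pace = "fast", d2_l = 0.1)
#' feedback_signal(initial_state(p), p)  # 1 / (2 * 0.87)
#' @export
feedback_signal <- function(state, params) {
  c2 <- if (!is.null(names(state))) state[["c2"]] else state[2]
  if (c2 < 0) stop("c2 must be non-negative", call. = FALSE)
  1 / (1 + params$k_c * c2)
}

#' Marrow-crowding death rate
#'
#' Resident marrow cells (HSC, LSC and non-proliferating leukemic cells)
#' die at an additional rate once total marrow cellularity
#' \eqn{x = c_1 + l_1 + l_2} exceeds its physiological equilibrium:
#' \eqn{d(x) = 10^{-10} \max(0, x - 4 \times 10^9)} per day.
#'
#' @param x marrow cellularity (cells/kg), scalar or vector.
#' @param params an [aml_parameters()] object.
#' @return Death rate (1/day), zero at or below the threshold.
#' @examples
#' p <- aml_parameters(pace = "fast", d2_l = 0.1)
#' crowding_death_rate(5e9, p)  # 0.1 per day
#' @export
crowding_death_rate <- function(x, params) {
  if (any(x < 0)) stop("marrow cellularity must be non-negative",
                       call. = FALSE)
  params$crowding_coeff * pmax(0, x - params$crowding_threshold)
}

#' Bone-marrow blast fraction
#'
#' The fraction of leukemic cells among marrow-resident cells,
#' \eqn{(l_1 + l_2) / (c_1 + l_1 + l_2)}. Clinically no routine distinction
#' is made between leukemic stem cells and their non-proliferating progeny,
#' so both count as blasts. When the marrow is essentially empty (total
#' marrow cellularity below the extinction threshold, i.e. less than one
#' cell in the patient) the fraction is not evaluable and `NA` is returned;
#' downstream remission logic treats this as no remission.
#'
#' @param state numeric state vector `c(c1, c2, l1, l2)` (named or
#'   positional).
#' @param extinction_threshold marrow cellularity below which the fraction
#'   is not evaluable (cells/kg).
#' @return Fraction in \[0, 1\], or `NA` if not evaluable.
#' @examples
#' blast_fraction(c(c1 = 8e8, c2 = 1e9, l1 = 1e8, l2 = 1e8))  # 0.2
#' @export
blast_fraction <- function(state, extinction_threshold = 1 / 70) {
  st <- .state_vec(state)
  x <- st[1] + st[3] + st[4]
  if (x < extinction_threshold) return(NA_real_)
  (st[3] + st[4]) / x
}

#' Right-hand side of the hematopoiesis/AML system
#'
#' Evaluates the rates of change of the four compartments under the
#' feedback-regulated self-renewal model with log-kill chemotherapy terms.
#' Cytarabine-like therapy (`k_cyt`) kills proliferating cells in
#' proportion to their proliferation rate; anthracycline-like therapy
#' (`k_anthra`) kills proliferating cells via the proliferation rate and
#' non-proliferating cells directly. Crowding death applies to the
#' marrow-resident compartments (c1, l1, l2) but not to circulating
#' differentiated healthy cells (c2).
#'
#' @param state numeric state vector `c(c1, c2, l1, l2)`, all non-negative.
#' @param params an [aml_parameters()] object.
#' @param chemo numeric vector `c(k_cyt, k_anthra)` of active therapy
#'   intensities (1/day); `c(0, 0)` means no active therapy.
#' @return Named numeric vector of derivatives (cells/kg/day).
#' @examples
#' p <- aml_parameters(pace = "fast", d2_l = 0.1)
#' aml_derivatives(initial_state(p, l1 = 0), p)  # all zero: steady state
#' @export
aml_derivatives <- function(state, params, chemo = c(k_cyt = 0, k_anthra = 0)) {
  st <- .state_vec(state)
  if (any(st < 0))
    stop("invalid state: all compartments must be non-negative",
         call. = FALSE)
  if (any(chemo < 0))
    stop("chemotherapy intensities must be non-negative", call. = FALSE)
  d <- .aml_rhs(0, st, .rhs_parms(params, chemo[1], chemo[2]))[[1]]
  names(d) <- c("c1", "c2", "l1", "l2")
  d
}

# coerce a (possibly named) state to positional c(c1, c2, l1, l2)
.state_vec <- function(state) {
  if (!is.null(names(state)) &&
      all(c("c1", "c2", "l1", "l2") %in% names(state)))
    return(unname(state[c("c1", "c2", "l1", "l2")]))
  unname(state[1:4])
}

# flat parameter vector consumed by the deSolve right-hand side
.rhs_parms <- function(params, k_cyt = 0, k_anthra = 0) {
  c(a_c = params$a_c, p_c = params$p_c, a_l = params$a_l, p_l = params$p_l,
    d2_c = params$d2_c, d2_l = params$d2_l, k_c = params$k_c,
    cc = params$crowding_coeff, ct = params$crowding_threshold,
    kcyt = k_cyt, kanthra = k_anthra)
}

# deSolve-style RHS; p is the vector built by .rhs_parms. Kept positional
# and allocation-light: it is the innermost loop of every simulation.
.aml_rhs <- function(t, y, p) {
  s <- 1 / (1 + p[7] * y[2])
  x <- y[1] + y[3] + y[4]
  d <- p[8] * max(0, x - p[9])
  dc1 <- (2 * p[1] * s - 1 - p[10] - p[11]) * p[2] * y[1] - d * y[1]
  dc2 <- 2 * p[2] * y[1] - 2 * p[1] * p[2] * s * y[1] -
    p[5] * y[2] - p[11] * y[2]
  dl1 <- (2 * p[3] * s - 1 - p[10] - p[11]) * p[4] * y[3] - d * y[3]
  dl2 <- 2 * p[4] * y[3] - 2 * p[3] * s * p[4] * y[3] -
    p[6] * y[4] - d * y[4] - p[11] * y[4]
  list(c(dc1, dc2, dl1, dl2))
}
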