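#' Sweep a grid of therapy-intensity combinations
#'
#' Simulates every combination of cytarabine-like and anthracycline-like
#' intensity on a grid (the reference analysis uses 0 to 10 in steps of
#' 0.1 on both axes, 10,201 combinations) for one leukemia and one study
#' arm, and collects the clinical endpoints of each cell. The pre-diagnosis
#' phase is identical across cells and is simulated once.
#'
#' @param params an [aml_parameters()] object.
#' @param policy a [regimen_policy()] or "standard"/"evaluation".
#' @param k_cyt,k_anthra strictly increasing grid axes (1/day).
#' @param config a [sim_config()]; use `horizon = 5000` for the slow pace.
#' @param progress print a progress message every completed axis row.
#' @return An object of class `aml_sweep`: a data frame with one row per
#'   grid cell (columns `k_cyt`, `k_anthra` plus the outcome-record
#'   columns of [extract_outcome()]), with the axes, arm and parameters as
#'   attributes. Summarise with [summarize_sweep()] or `summary()`.
#' @examples
#' \donttest{
#' p <- aml_parameters(pace = "fast", d2_l = 0.113)
#' sw <- sweep_intensities(p, "standard", k_cyt = seq(0, 10, 2.5),
#'                         k_anthra = seq(0, 10, 2.5))
#' summary(sw)
#' }
#' @export
sweep_intensities <- function(params, policy = "standard",
                              k_cyt = seq(0, 10, by = 0.1),
                              k_anthra = seq(0, 10, by = 0.1),
                              config = sim_config(), progress = FALSE) {
  if (is.character(policy)) policy <- regimen_policy(policy)
  if (is.unsorted(k_cyt, strictly = TRUE) ||
      is.unsorted(k_anthra, strictly = TRUE))
    stop("grid axes must be strictly increasing", call. = FALSE)
  presim <- .presimulate(params, config, initial_state(params))
  if (is.na(presim$diagnosis_day))
    stop("this leukemia never reaches the diagnostic threshold within ",
         "the horizon; nothing to treat", call. = FALSE)
  grid <- expand.grid(k_cyt = k_cyt, k_anthra = k_anthra,
                      KEEP.OUT.ATTRS = FALSE)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    traj <- simulate_therapy(params, policy, grid$k_cyt[i],
                             grid$k_anthra[i], config, presim = presim)
    res[[i]] <- extract_outcome(traj)
    if (progress && i %% length(k_cyt) == 0)
      message(sprintf("sweep: %d / %d cells", i, nrow(grid)))
  }
  out <- cbind(grid, do.call(rbind, res))
  structure(out, class = c("aml_sweep", "data.frame"),
            k_cyt_axis = k_cyt, k_anthra_axis = k_anthra,
            arm = policy$arm, params = params, horizon = config$horizon)
}

#' Summary statistics of an intensity sweep
#'
#' Computes the paper-style outcome table of a sweep: the therapeutic width
#' (share of combinations reaching complete remission) and the over- and
#' undertreatment shares, the split of remissions into quasi-infinite /
#' short / other, the time-to-CR range, and the share of earliest-possible
#' remissions (reported both as a share of all combinations and of
#' CR-achieving combinations, since either denominator is of interest).
#'
#' @param sweep an `aml_sweep`.
#' @return A list of class `aml_sweep_summary`; percentages are of all grid
#'   cells unless suffixed `_of_cr`.
#' @export
summarize_sweep <- function(sweep) {
  n <- nrow(sweep)
  pct <- function(k) 100 * k / n
  eff <- sweep$classification == "effective"
  ttcr <- sweep$time_to_cr[eff]
  min_ttcr <- if (any(eff)) min(ttcr) else NA_real_
  out <- list(
    n_cells = n,
    arm = attr(sweep, "arm"),
    therapeutic_width_pct = pct(sum(eff)),
    overtreatment_pct = pct(sum(sweep$classification == "overtreatment")),
    undertreatment_pct = pct(sum(sweep$classification == "undertreatment")),
    quasi_infinite_pct = pct(sum(sweep$cr_class == "quasi_infinite",
                                 na.rm = TRUE)),
    short_cr_pct = pct(sum(sweep$cr_class == "short", na.rm = TRUE)),
    other_cr_pct = pct(sum(sweep$cr_class == "other", na.rm = TRUE)),
    time_to_cr_range = if (any(eff)) range(ttcr) else c(NA_real_, NA_real_),
    earliest_cr_pct = pct(sum(eff & sweep$time_to_cr == min_ttcr)),
    earliest_cr_pct_of_cr = if (any(eff))
      100 * sum(ttcr == min_ttcr) / sum(eff) else NA_real_)
  class(out) <- "aml_sweep_summary"
  out
}

#' @export
summary.aml_sweep <- function(object, ...) summarize_sweep(object)

#' @export
print.aml_sweep_summary <- function(x, ...) {
  cat(sprintf("Intensity sweep, %s arm (%d combinations)\n",
              x$arm, x$n_cells))
  cat(sprintf("  Time to CR (range):    %g to %g days\n",
              x$time_to_cr_range[1], x$time_to_cr_range[2]))
  cat(sprintf("  Therapeutic width:     %.2f%%\n", x$therapeutic_width_pct))
  cat(sprintf("  Overtreatment region:  %.2f%%\n", x$overtreatment_pct))
  cat(sprintf("  Undertreatment region: %.2f%%\n", x$undertreatment_pct))
  cat(sprintf("  quasi-infinite CR %.2f%% | short CR %.2f%% | other %.2f%%\n",
              x$quasi_infinite_pct, x$short_cr_pct, x$other_cr_pct))
  cat(sprintf("  earliest CR (day %g): %.2f%% of all, %.2f%% of CR cells\n",
              x$time_to_cr_range[1], x$earliest_cr_pct,
              x$earliest_cr_pct_of_cr))
  invisible(x)
}

#' @export
print.aml_sweep <- function(x, ...) {
  cat(sprintf("aml_sweep: %d x %d grid, %s arm\n",
              length(attr(x, "k_cyt_axis")), length(attr(x, "k_anthra_axis")),
              attr(x, "arm")))
  print(summarize_sweep(x))
  invisible(x)
}

#' Write a sweep to a tab-separated file
#'
#' One row per grid cell with the arm and pace parameters attached.
#'
#' @param sweep an `aml_sweep`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  p <- attr(sweep, "params")
  df <- cbind(data.frame(arm = attr(sweep, "arm"), a_l = p$a_l, p_l = p$p_l),
              as.data.frame(sweep))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compare the two study arms cell by cell
#'
#' Builds the "Evaluation - Standard" difference maps over a common
#' intensity grid, for time to CR and for CR duration, with the region
#' semantics of the reference analysis: a cell counts for an arm when that
#' arm is strictly better there (shorter time to CR / longer CR duration)
#' or when it uniquely achieves CR; cells where neither arm achieves CR, or
#' both do equally, count as no difference.
#'
#' @param sweep_std,sweep_eval `aml_sweep`s of the standard and evaluation
#'   arm over identical grids.
#' @return A list of class `aml_arm_comparison` with components
#'   `time_to_cr` and `cr_duration`, each holding `no_difference_pct`,
#'   `std_better_pct`, `eval_better_pct`, the share of arm-unique CRs, and
#'   a per-cell data frame (`cells`) with the differences.
#' @export
compare_arms <- function(sweep_std, sweep_eval) {
  if (!identical(attr(sweep_std, "k_cyt_axis"), attr(sweep_eval, "k_cyt_axis")) ||
      !identical(attr(sweep_std, "k_anthra_axis"),
                 attr(sweep_eval, "k_anthra_axis")))
    stop("the two sweeps use different grids", call. = FALSE)
  n <- nrow(sweep_std)
  cr_s <- sweep_std$classification == "effective"
  cr_e <- sweep_eval$classification == "effective"

  one_metric <- function(val_s, val_e, better = c("lower", "higher")) {
    better <- match.arg(better)
    diff <- ifelse(cr_s & cr_e, val_e - val_s, NA_real_)
    s_wins <- (cr_s & !cr_e) |
      (cr_s & cr_e & (if (better == "lower") diff > 0 else diff < 0))
    e_wins <- (!cr_s & cr_e) |
      (cr_s & cr_e & (if (better == "lower") diff < 0 else diff > 0))
    list(no_difference_pct = 100 * sum(!s_wins & !e_wins) / n,
         std_better_pct = 100 * sum(s_wins) / n,
         eval_better_pct = 100 * sum(e_wins) / n,
         std_unique_cr_pct = 100 * sum(cr_s & !cr_e) / n,
         eval_unique_cr_pct = 100 * sum(!cr_s & cr_e) / n,
         cells = data.frame(k_cyt = sweep_std$k_cyt,
                            k_anthra = sweep_std$k_anthra,
                            cr_std = cr_s, cr_eval = cr_e,
                            difference = diff))
  }
  structure(list(
    time_to_cr = one_metric(sweep_std$time_to_cr, sweep_eval$time_to_cr,
                            "lower"),
    cr_duration = one_metric(sweep_std$cr_duration, sweep_eval$cr_duration,
                             "higher")),
    class = "aml_arm_comparison")
}

#' @export
print.aml_arm_comparison <- function(x, ...) {
  for (m in c("time_to_cr", "cr_duration")) {
    cat(sprintf("%s (evaluation - standard):\n", m))
    cat(sprintf("  no difference %.2f%% | standard better %.2f%% | evaluation better %.2f%%\n",
                x[[m]]$no_difference_pct, x[[m]]$std_better_pct,
                x[[m]]$eval_better_pct))
    cat(sprintf("  arm-unique CR: standard %.2f%%, evaluation %.2f%%\n",
                x[[m]]$std_unique_cr_pct, x[[m]]$eval_unique_cr_pct))
  }
  invisible(x)
}

#' Time-to-diagnosis landscape over leukemia growth parameters
#'
#' Simulates the untreated onset of every combination of leukemic
#' self-renewal and proliferation rate on a grid and records the time from
#' one seeded LSC to the 20% diagnostic blast threshold. Combinations whose
#' self-renewal does not exceed the healthy value never produce a
#' diagnosable leukemia (`NA`).
#'
#' @param a_l,p_l grid axes within \[0, 1\] and \[0, 2\].
#' @param d2_l clearance rate of non-proliferating leukemic cells.
#' @param horizon last simulated day (5000 in the reference analysis).
#' @param config a [sim_config()].
#' @return A data frame with columns `a_l`, `p_l`, `diagnosis_day`.
#' @export
pace_landscape <- function(a_l = seq(0, 1, by = 0.1),
                           p_l = seq(0, 2, by = 0.2),
                           d2_l, horizon = 5000, config = sim_config()) {
  config$horizon <- horizon
  grid <- expand.grid(a_l = a_l, p_l = p_l, KEEP.OUT.ATTRS = FALSE)
  grid$diagnosis_day <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    params <- aml_parameters(a_l = grid$a_l[i], p_l = grid$p_l[i],
                             d2_l = d2_l)
    pre <- .presimulate(params, config, initial_state(params))
    grid$diagnosis_day[i] <- pre$diagnosis_day
  }
  grid
}

#' Calibrate the clearance rate of non-proliferating leukemic cells
#'
#' The clearance rate `d2_l` is the one scalar of the model without a
#' published value. It is pinned by requiring that the untreated fast-pace
#' leukemia (self-renewal 1, proliferation 2/day) reaches the 20%
#' diagnostic threshold on day 63. Because the diagnosis day moves in whole
#' days, a whole interval of `d2_l` is compatible with the anchor; the
#' routine verifies monotonicity over the bracket, bisects both interval
#' edges and returns the midpoint together with the interval.
#'
#' @param anchor_day target diagnosis day of the untreated fast leukemia.
#' @param bracket search interval for `d2_l` (1/day).
#' @param a_l,p_l leukemia used for the anchor (fast pace).
#' @param tol absolute bisection tolerance on `d2_l`.
#' @param config a [sim_config()].
#' @return A list with `d2_l` (interval midpoint), `interval`, and
#'   `anchor_day`.
#' @examples
#' \donttest{
#' calibrate_d2l()$d2_l
#' }
#' @export
calibrate_d2l <- function(anchor_day = 63, bracket = c(0.005, 1),
                          a_l = 1, p_l = 2, tol = 1e-4,
                          config = sim_config(horizon = 500)) {
  dx_of <- function(d2l) {
    params <- aml_parameters(a_l = a_l, p_l = p_l, d2_l = d2l)
    .presimulate(params, config, initial_state(params))$diagnosis_day
  }
  probe <- vapply(seq(bracket[1], bracket[2], length.out = 5), dx_of,
                  numeric(1))
  if (is.unsorted(probe))
    stop("diagnosis day is not monotone in d2_l over the bracket",
         call. = FALSE)
  lo <- dx_of(bracket[1])
  hi <- dx_of(bracket[2])
  if (is.na(lo) || lo > anchor_day || is.na(hi) || hi < anchor_day)
    stop(sprintf("no d2_l in [%g, %g] yields diagnosis on day %d (bracket gives %s..%s)",
                 bracket[1], bracket[2], anchor_day, lo, hi), call. = FALSE)
  # largest d2_l with diagnosis day < anchor (lower interval edge) and
  # largest with diagnosis day <= anchor (upper edge)
  bisect_edge <- function(pred) {
    a <- bracket[1]; b <- bracket[2]
    while (b - a > tol) {
      m <- (a + b) / 2
      if (pred(dx_of(m))) a <- m else b <- m
    }
    (a + b) / 2
  }
  lower <- bisect_edge(function(d) d < anchor_day)
  upper <- bisect_edge(function(d) d <= anchor_day)
  if (upper <= lower)
    stop("bracket cannot produce the anchor day", call. = FALSE)
  list(d2_l = (lower + upper) / 2, interval = c(lower, upper),
       anchor_day = anchor_day)
}
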