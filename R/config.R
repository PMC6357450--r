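#' Load a run configuration from a YAML file
#'
#' A run configuration collects everything needed to reproduce a sweep or a
#' single simulation: the leukemia (a pace preset or explicit `a_l`/`p_l`),
#' the study arm, the intensity grid, the horizon, solver tolerances and
#' the `d2_l` value (or the directive `d2_l: calibrate`). Missing keys get
#' the reference defaults: grid 0-10 in steps of 0.1 on both axes, horizon
#' 2000 days (5000 for the slow pace). All validation failures are reported
#' together.
#'
#' @param path path to a YAML file.
#' @return A validated list of class `aml_run_config` with elements `pace`,
#'   `a_l`, `p_l`, `arm`, `grid` (`min`, `max`, `step`), `horizon`,
#'   `rtol`, `atol`, `d2_l` (numeric or the string "calibrate").
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  as_run_config(raw)
}

#' Build a run configuration from a list
#'
#' @param x named list with the fields of [load_run_config()].
#' @return A validated `aml_run_config`.
#' @export
as_run_config <- function(x = list()) {
  errs <- character()
  pace <- x$pace
  if (!is.null(pace) && !pace %in% c("fast", "intermediate", "slow"))
    errs <- c(errs, "pace must be one of fast/intermediate/slow")
  a_l <- x$a_l
  p_l <- x$p_l
  if (!is.null(pace) && is.null(a_l)) {
    preset <- pace_preset(pace)
    a_l <- preset$a_l
    p_l <- preset$p_l
  }
  if (is.null(a_l) || is.null(p_l))
    errs <- c(errs, "supply a pace preset or explicit a_l and p_l")
  if (!is.null(a_l) && (a_l < 0 || a_l > 1))
    errs <- c(errs, sprintf("a_l = %g outside [0, 1]", a_l))
  if (!is.null(p_l) && (p_l < 0 || p_l > 2))
    errs <- c(errs, sprintf("p_l = %g outside [0, 2]", p_l))
  arm <- if (is.null(x$arm)) "standard" else x$arm
  if (!arm %in% c("standard", "evaluation"))
    errs <- c(errs, "arm must be standard or evaluation")
  grid <- utils::modifyList(list(min = 0, max = 10, step = 0.1),
                            if (is.null(x$grid)) list() else x$grid)
  if (grid$min < 0 || grid$max <= grid$min || grid$step <= 0)
    errs <- c(errs, "grid must satisfy 0 <= min < max, step > 0")
  horizon <- x$horizon
  if (is.null(horizon))
    horizon <- if (!is.null(pace) && pace == "slow") 5000 else 2000
  if (horizon < 1) errs <- c(errs, "horizon must be at least 1 day")
  d2_l <- if (is.null(x$d2_l)) "calibrate" else x$d2_l
  if (!(identical(d2_l, "calibrate") || (is.numeric(d2_l) && d2_l >= 0)))
    errs <- c(errs, "d2_l must be a non-negative number or \"calibrate\"")
  if (length(errs))
    stop("invalid run configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  structure(list(pace = pace, a_l = a_l, p_l = p_l, arm = arm, grid = grid,
                 horizon = horizon,
                 rtol = if (is.null(x$rtol)) 1e-8 else x$rtol,
                 atol = if (is.null(x$atol)) 1e-4 else x$atol,
                 d2_l = d2_l),
            class = "aml_run_config")
}

#' Save a run configuration to a YAML file
#'
#' Round-trips with [load_run_config()].
#'
#' @param config an `aml_run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# materialise the pieces of a run configuration
.config_pieces <- function(rc) {
  d2l <- if (identical(rc$d2_l, "calibrate")) calibrate_d2l()$d2_l else rc$d2_l
  list(params = aml_parameters(a_l = rc$a_l, p_l = rc$p_l, d2_l = d2l),
       policy = regimen_policy(rc$arm),
       axis = seq(rc$grid$min, rc$grid$max, by = rc$grid$step),
       config = sim_config(horizon = rc$horizon, rtol = rc$rtol,
                           atol = rc$atol))
}

#' Reproduce the full induction-regimen comparison
#'
#' Runs the whole analysis pipeline: calibrates `d2_l` from the fast-pace
#' diagnosis anchor, sweeps the intensity grid for the requested paces and
#' both study arms, compares the arms, and writes everything to `outdir`:
#' per-cell sweep tables (TSV), an outcome summary table, difference-map
#' fractions, heatmap figures and a machine-readable JSON report. With the
#' default `step = 0.1` this is the full 10,201-cell grid per sweep and
#' takes on the order of an hour; coarser steps give quick approximations.
#'
#' @param outdir output directory (created if needed).
#' @param paces subset of c("fast", "intermediate", "slow").
#' @param step grid step on both intensity axes.
#' @param d2_l fixed value, or NULL to calibrate.
#' @param figures write heatmap PNGs (requires ggplot2).
#' @return Invisibly, a list with the calibration, summaries and
#'   comparisons.
#' @export
run_induction_study <- function(outdir, paces = c("fast", "intermediate", "slow"),
                                step = 0.1, d2_l = NULL, figures = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cal <- if (is.null(d2_l)) calibrate_d2l() else
    list(d2_l = d2_l, interval = c(NA, NA), anchor_day = NA)
  axis <- seq(0, 10, by = step)
  summaries <- list()
  comparisons <- list()
  for (pace in paces) {
    horizon <- pace_preset(pace)$default_horizon
    params <- aml_parameters(pace = pace, d2_l = cal$d2_l)
    cfg <- sim_config(horizon = horizon)
    sweeps <- list()
    for (arm in c("standard", "evaluation")) {
      message(sprintf("sweeping %s pace, %s arm (%d cells)",
                      pace, arm, length(axis)^2))
      sw <- sweep_intensities(params, arm, axis, axis, cfg)
      write_sweep(sw, file.path(outdir, sprintf("sweep_%s_%s.tsv", pace, arm)))
      summaries[[paste(pace, arm, sep = "_")]] <- summarize_sweep(sw)
      sweeps[[arm]] <- sw
      if (figures) {
        for (metric in c("time_to_cr", "cr_duration")) {
          f <- file.path(outdir, sprintf("%s_%s_%s.png", metric, pace, arm))
          grDevices::png(f, width = 1400, height = 1200, res = 200)
          print(plot_sweep(sw, metric))
          grDevices::dev.off()
        }
      }
    }
    comparisons[[pace]] <- compare_arms(sweeps$standard, sweeps$evaluation)
  }
  summary_tbl <- do.call(rbind, lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    data.frame(run = nm,
               time_to_cr_min = s$time_to_cr_range[1],
               time_to_cr_max = s$time_to_cr_range[2],
               therapeutic_width_pct = round(s$therapeutic_width_pct, 2),
               overtreatment_pct = round(s$overtreatment_pct, 2),
               undertreatment_pct = round(s$undertreatment_pct, 2),
               quasi_infinite_pct = round(s$quasi_infinite_pct, 2),
               short_cr_pct = round(s$short_cr_pct, 2))
  }))
  utils::write.table(summary_tbl, file.path(outdir, "outcome_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(d2_l = cal, summaries = summaries,
                 comparisons = lapply(comparisons, function(cmp)
                   lapply(cmp, function(m) m[setdiff(names(m), "cells")])))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
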