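#' Heatmap of a sweep endpoint over the intensity grid
#'
#' Displays time to CR or CR duration per intensity combination. Cells
#' without complete remission are drawn gray, mirroring the reference
#' figures (lower-left gray: undertreatment; upper-right gray:
#' overtreatment).
#'
#' @param sweep an `aml_sweep`.
#' @param metric "time_to_cr" or "cr_duration".
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, metric = c("time_to_cr", "cr_duration")) {
  metric <- match.arg(metric)
  df <- as.data.frame(sweep)
  df$value <- df[[metric]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k_cyt, y = .data$k_anthra)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_viridis_c(na.value = "gray60",
                                  name = sprintf("%s (days)", metric)) +
    ggplot2::labs(x = "cytarabine-like intensity k_cyt (1/day)",
                  y = "anthracycline-like intensity k_anthra (1/day)",
                  title = sprintf("%s, %s arm (gray: no CR)",
                                  metric, attr(sweep, "arm"))) +
    ggplot2::theme_minimal()
}

#' Difference map between the two study arms
#'
#' "Evaluation - Standard" per intensity combination, with arm-unique CR
#' regions in distinct colors: cells where only the standard arm achieves
#' CR in blue, cells where only the evaluation arm does in red; gray where
#' neither does.
#'
#' @param comparison an `aml_arm_comparison` from [compare_arms()].
#' @param metric "time_to_cr" or "cr_duration".
#' @return A ggplot object.
#' @export
plot_arm_difference <- function(comparison,
                                metric = c("time_to_cr", "cr_duration")) {
  metric <- match.arg(metric)
  df <- comparison[[metric]]$cells
  df$region <- ifelse(df$cr_std & !df$cr_eval, "standard only",
                      ifelse(!df$cr_std & df$cr_eval, "evaluation only",
                             ifelse(df$cr_std & df$cr_eval, "both", "neither")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k_cyt, y = .data$k_anthra)) +
    ggplot2::geom_raster(data = df[df$region == "both", ],
                         ggplot2::aes(fill = .data$difference)) +
    ggplot2::geom_raster(data = df[df$region == "standard only", ],
                         fill = "#2166ac") +
    ggplot2::geom_raster(data = df[df$region == "evaluation only", ],
                         fill = "#b2182b") +
    ggplot2::geom_raster(data = df[df$region == "neither", ],
                         fill = "gray60") +
    ggplot2::scale_fill_gradient2(low = "#1a9850", mid = "white",
                                  high = "#d73027", name = "eval - std (days)") +
    ggplot2::labs(x = "cytarabine-like intensity k_cyt (1/day)",
                  y = "anthracycline-like intensity k_anthra (1/day)",
                  title = sprintf("%s difference (blue: standard-only CR, red: evaluation-only CR)",
                                  metric)) +
    ggplot2::theme_minimal()
}

#' Trajectory panel of one simulated patient
#'
#' Cell abundances (log scale) and blast fraction over time with therapy
#' windows shaded.
#'
#' @param traj an `aml_trajectory`.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj) {
  df <- as.data.frame(traj)
  long <- data.frame(
    day = rep(df$day, 4),
    compartment = rep(c("c1 (HSC)", "c2 (differentiated)",
                        "l1 (LSC)", "l2 (leukemic non-prolif.)"),
                      each = nrow(df)),
    cells = c(df$c1, df$c2, df$l1, df$l2))
  long <- long[long$cells > 0, ]
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$cells,
                                           color = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "day", y = "cells/kg") +
    ggplot2::theme_minimal()
  for (crs in attr(traj, "courses"))
    gg <- gg + ggplot2::annotate("rect", xmin = crs$start_day,
                                 xmax = crs$start_day + crs$cyt_duration,
                                 ymin = -Inf, ymax = Inf, alpha = 0.15)
  gg
}
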