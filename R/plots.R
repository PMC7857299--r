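#' Manhattan-style plot of a window scan
#'
#' @param object A `window_scan` tibble.
#' @param stat Column to plot (default `"fst"`).
#' @param threshold Optional horizontal threshold line (e.g. a null
#'   percentile).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.window_scan <- function(object, stat = "fst", threshold = NULL,
                                 ...) {
  df <- dplyr::mutate(object, mid = (.data$start + .data$end) / 2)
  gg <- ggplot2::ggplot(df,
          ggplot2::aes(x = .data$mid / 1e3, y = .data[[stat]])) +
    ggplot2::geom_point(size = 0.4, alpha = 0.7) +
    ggplot2::labs(x = "Position (kb)", y = toupper(stat)) +
    ggplot2::theme_minimal()
  if (!is.null(threshold))
    gg <- gg + ggplot2::geom_hline(yintercept = threshold,
                                   linetype = "dashed", colour = "grey40")
  gg
}

#' Plot binned summary-statistic profiles around outliers
#'
#' One panel per statistic, lines per scenario, ribbons for the bootstrap
#' band.
#'
#' @param object A `profile_aggregate` tibble (possibly several scenarios
#'   bound together, as in `experiment_profiles()$profiles`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.profile_aggregate <- function(object, ...) {
  ggplot2::ggplot(object,
      ggplot2::aes(x = .data$bin_mid / 1e3, y = .data$mean,
                   colour = .data$scenario, fill = .data$scenario)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~stat, scales = "free_y") +
    ggplot2::labs(x = "Distance from outlier center (kb)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Allele-frequency trajectories of selected mutations
#'
#' Deme-1 frequencies as solid lines, deme-2 as dashed, one colour per
#' mutation.
#'
#' @param traj Trajectory tibble (`wf_run()$trajectories`).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(traj) {
  long <- tidyr::pivot_longer(traj, c("freq_deme1", "freq_deme2"),
                              names_to = "deme", names_prefix = "freq_",
                              values_to = "freq")
  ggplot2::ggplot(long,
      ggplot2::aes(x = .data$generation, y = .data$freq,
                   colour = factor(.data$mutation),
                   linetype = .data$deme)) +
    ggplot2::geom_line(show.legend = c(colour = FALSE, linetype = TRUE)) +
    ggplot2::scale_linetype_manual(values = c(deme1 = "solid",
                                              deme2 = "dashed")) +
    ggplot2::labs(x = "Generation", y = "Allele frequency",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sweep_timecourse <- function(object, ...) {
  df <- dplyr::mutate(object$scans,
                      mid = (.data$start + .data$end) / 2)
  ggplot2::ggplot(df,
      ggplot2::aes(x = .data$mid / 1e3, y = .data$fst,
                   group = .data$generation,
                   colour = .data$generation)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "Position (kb)", y = "F_ST",
                  colour = "Generation") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
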