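# ggplot2 visualizations for the main result types.

#' Plot a precision-recall curve
#'
#' @param object a [pr_curve()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.jellytag_pr_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Recall", y = "Precision",
      subtitle = sprintf("AUPRC %.3f (chance %.3f)",
                         attr(object, "auprc"), attr(object, "prevalence"))) +
    ggplot2::theme_minimal()
}

#' Plot the fold-averaged precision-recall curve of a CV report
#'
#' Marks the equal-error-rate threshold on the averaged curve.
#'
#' @param object a [nested_cv()] report.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.jellytag_cv_report <- function(object, ...) {
  av <- object$avg_curve
  eer_row <- av[which.min(abs(av$threshold - object$eer_threshold)), ]
  ggplot2::ggplot(av, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = eer_row, color = "red", size = 2) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Recall", y = "Precision",
      subtitle = sprintf("AUPRC %.3f +/- %.3f; EER threshold %.1f",
                         object$mean_auprc, object$se_auprc,
                         object$eer_threshold)) +
    ggplot2::theme_minimal()
}

#' Kinematics overview panel
#'
#' Heading, pitch, roll and normalized ODBA over a deployment, downsampled
#' for plotting.
#'
#' @param kin result of [process_kinematics()].
#' @param every plot every `every`-th sample (default 100, i.e. 1 Hz at a
#'   100 Hz record).
#' @return a ggplot.
#' @export
plot_kinematics <- function(kin, every = 100) {
  idx <- seq(1, nrow(kin$euler), by = every)
  df <- tibble(
    time = kin$euler$time[idx],
    heading = kin$euler$heading[idx],
    pitch = kin$euler$pitch[idx],
    roll = kin$euler$roll[idx],
    odba_norm = kin$signals$odba_norm[idx]
  ) |>
    tidyr::pivot_longer(-"time", names_to = "channel", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Export a kinematics CSV for external plotting
#'
#' Writes time, heading, pitch, roll and the normalized ODBA/PDBA channels.
#'
#' @param kin result of [process_kinematics()].
#' @param path output CSV path.
#' @param every write every `every`-th sample (default 1 = all).
#' @export
write_kinematics_csv <- function(kin, path, every = 1) {
  idx <- seq(1, nrow(kin$euler), by = every)
  readr::write_csv(tibble(
    time = kin$euler$time[idx],
    heading = kin$euler$heading[idx],
    pitch = kin$euler$pitch[idx],
    roll = kin$euler$roll[idx],
    odba_norm = kin$signals$odba_norm[idx],
    pdba_norm = kin$signals$pdba_norm[idx]
  ), path, progress = FALSE)
  invisible(kin)
}
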