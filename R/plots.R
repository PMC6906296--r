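# ggplot2 views of the main result types.

#' Heatmap of a feature-by-measure correlation table
#'
#' Tiles coloured by Spearman rho, starred at q <= 0.05 (one star) and
#' q <= 0.01 (two stars).
#'
#' @param cortab an `ms_cortab` from [correlation_table()].
#' @return a ggplot object.
#' @export
plot_correlation_table <- function(cortab) {
  df <- tibble::as_tibble(cortab)
  df$stars <- dplyr::case_when(df$sig_q01 ~ "**", df$sig_q05 ~ "*",
                               TRUE ~ "")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$measure, y = .data$feature,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @rdname plot_correlation_table
#' @param object,... autoplot interface.
#' @export
autoplot.ms_cortab <- function(object, ...) plot_correlation_table(object)

#' Variability of the k-day median versus days observed
#'
#' Per-subject curves in grey, cohort mean in black.
#'
#' @param varcurve an `ms_varcurve` from [variability_vs_days()].
#' @return a ggplot object.
#' @export
plot_variability_curve <- function(varcurve) {
  df <- tibble::as_tibble(varcurve)
  subj <- df[df$subject != ".cohort", ]
  coh <- df[df$subject == ".cohort", ]
  ggplot2::ggplot(subj, ggplot2::aes(x = .data$k, y = .data$se_median,
                                     group = .data$subject)) +
    ggplot2::geom_line(colour = "grey70") +
    ggplot2::geom_line(data = coh, colour = "black", linewidth = 1) +
    ggplot2::labs(x = "days aggregated (k)",
                  y = "RMS deviation of k-day median") +
    ggplot2::theme_minimal()
}

#' @rdname plot_variability_curve
#' @param object,... autoplot interface.
#' @export
autoplot.ms_varcurve <- function(object, ...) plot_variability_curve(object)

#' Plot a sway track
#' @param track tibble with `ml_mm`, `ap_mm`.
#' @return a ggplot object.
#' @export
plot_sway_track <- function(track) {
  ggplot2::ggplot(track, ggplot2::aes(x = .data$ml_mm, y = .data$ap_mm)) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "mediolateral (mm)", y = "anterior-posterior (mm)") +
    ggplot2::theme_minimal()
}

#' Plot a yaw-rate trace with detected turns
#' @param data tibble with `t`, `yaw`.
#' @param turns optional [detect_turns()] result to shade.
#' @return a ggplot object.
#' @export
plot_turn_trace <- function(data, turns = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$t, y = .data$yaw)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "yaw rate (deg/s)") +
    ggplot2::theme_minimal()
  if (!is.null(turns) && nrow(turns) > 0) {
    p <- p + ggplot2::geom_rect(
      data = turns,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "#2166ac")
  }
  p
}
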