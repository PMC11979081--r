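#' Plot a pressure trace
#'
#' @param object A [bp_trace()].
#' @param window Optional numeric length-2 vector restricting the plotted
#'   time window, seconds.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bp_trace
#' @export
autoplot.bp_trace <- function(object, window = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(window)) {
    df <- dplyr::filter(df, .data$time_s >= window[1], .data$time_s <= window[2])
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$pressure_mmHg)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Pressure (mmHg)") +
    ggplot2::theme_minimal()
}

#' Plot an ensemble beat: retained and rejected cycles plus the representative
#'
#' @param object An `ensemble_beat` (see [ensemble_average()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ensemble_beat
#' @export
autoplot.ensemble_beat <- function(object, ...) {
  rep_df <- dplyr::mutate(object$representative, what = "representative")
  ggplot2::ggplot(rep_df,
                  ggplot2::aes(x = .data$time_s, y = .data$pressure_mmHg)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(
      x = "Time from fiducial (s)", y = "Pressure (mmHg)",
      title = sprintf("Representative beat (%d of %d cycles retained)",
                      object$n_retained, object$n_detected)
    ) +
    ggplot2::theme_minimal()
}

#' Waveform panel with shaded systolic and diastolic areas
#'
#' Visualises the morphometric panel: the representative beat with the
#' systolic (foot to dicrotic notch) and diastolic (notch to cycle end) areas
#' shaded, the notch marked, and SBP/DBP levels drawn.
#'
#' @param beat An `ensemble_beat`.
#' @param notch_index Optional known notch index; detected when omitted.
#' @return A ggplot object.
#' @export
plot_waveform_panel <- function(beat, notch_index = NULL) {
  stopifnot(inherits(beat, "ensemble_beat"))
  if (is.null(notch_index)) {
    notch <- detect_dicrotic_notch(beat)
    notch_index <- if (notch$found) notch$index else NA_integer_
  }
  ci <- beat_cycle_indices(beat)
  df <- beat$representative
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$pressure_mmHg)) +
    ggplot2::geom_line(linewidth = 0.8)
  if (!is.na(notch_index)) {
    sys_df <- df[ci$foot:notch_index, ]
    dia_df <- df[notch_index:ci$end, ]
    p <- p +
      ggplot2::geom_area(data = sys_df, fill = "grey80", alpha = 0.8) +
      ggplot2::geom_area(data = dia_df, fill = "grey55", alpha = 0.8) +
      ggplot2::geom_vline(xintercept = df$time_s[notch_index],
                          linetype = "dashed")
  }
  p +
    ggplot2::labs(x = "Time from fiducial (s)", y = "Pressure (mmHg)",
                  title = "Pulse waveform panel",
                  subtitle = "light grey: systolic area; dark grey: diastolic area (decay-constant window)") +
    ggplot2::theme_minimal()
}

#' Group-wise distribution of one cohort feature
#'
#' @param cohort A cohort tibble (see [generate_cohort()]).
#' @param feature Feature column (tidy evaluation).
#' @return A ggplot object (boxplots by circle-of-Willis group).
#' @export
plot_cohort_feature <- function(cohort, feature) {
  ggplot2::ggplot(cohort,
                  ggplot2::aes(x = factor(.data$cow_group), y = {{ feature }})) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "Circle of Willis group") +
    ggplot2::theme_minimal()
}
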