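#' Plot moment arms across a sweep
#'
#' One line per degree of freedom (and axis mode, if several are present) of
#' the normalized moment arm against the flexion-extension angle, faceted by
#' muscle. Positive values are extension / adduction / lateral rotation;
#' negative values flexion / abduction / medial rotation.
#'
#' @param object A `marm_records` tibble from [run_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.marm_records <- function(object, ...) {
  multi_mode <- dplyr::n_distinct(object$mode) > 1
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$fe_deg, y = .data$moment_arm_norm,
                 colour = factor(.data$dof, levels = DOFS))) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey55") +
    ggplot2::geom_line(if (multi_mode)
      ggplot2::aes(linetype = .data$mode) else NULL) +
    ggplot2::facet_wrap(~muscle) +
    ggplot2::labs(x = "hip flexion-extension angle (deg, + = extension)",
                  y = "moment arm / femur length", colour = "dof",
                  linetype = "mode") +
    ggplot2::theme_minimal()
  p
}

#' Plot summed functional-group moment arms
#'
#' Summed positive (extensor / adductor / lateral-rotator) and negative
#' (flexor / abductor / medial-rotator) normalized moment arms against
#' flexion-extension angle, faceted by degree of freedom.
#'
#' @param object A `marm_summary` from [summarize_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.marm_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    cols = c("summed_positive", "summed_negative_magnitude"),
    names_to = "side", values_to = "summed")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$fe_deg, y = .data$summed,
                               colour = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~factor(dof, levels = DOFS)) +
    ggplot2::labs(x = "hip flexion-extension angle (deg, + = extension)",
                  y = "summed |moment arm| / femur length",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot muscle-function classifications
#'
#' Muscle-by-dof tile map of the functional labels, annotated with the
#' interpolated zero-crossing angle for switching muscles.
#'
#' @param object A `marm_labels` from [classify_function()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.marm_labels <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$dof, levels = DOFS),
                               y = .data$muscle, fill = .data$label)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(
      ggplot2::aes(label = ifelse(is.na(.data$crossing_angle_deg), "",
                                  sprintf("%.0f", .data$crossing_angle_deg))),
      size = 3) +
    ggplot2::labs(x = "degree of freedom", y = NULL, fill = "function") +
    ggplot2::theme_minimal()
}
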