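#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated trial
#'
#' Bump position and true heading over time, with cue shift events marked.
#'
#' @param object A `ring_sim` from [simulate_trial()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ring_sim <- function(object, ...) {
  fr <- tidyr::pivot_longer(object$frames[c("t", "theta_true", "bump_pos")],
                            c("theta_true", "bump_pos"),
                            names_to = "series", values_to = "angle")
  p <- ggplot2::ggplot(fr, ggplot2::aes(.data$t, .data$angle,
                                        colour = .data$series)) +
    ggplot2::geom_point(size = 0.2) +
    ggplot2::scale_y_continuous(limits = c(-pi, pi),
                                breaks = c(-pi, 0, pi),
                                labels = c("-π", "0", "π")) +
    ggplot2::labs(x = "time (s)", y = "angle (rad)", colour = NULL) +
    ggplot2::theme_minimal()
  if (nrow(object$schedule$shift_events)) {
    p <- p + ggplot2::geom_vline(
      data = object$schedule$shift_events,
      ggplot2::aes(xintercept = .data$time), linetype = "dashed",
      colour = "grey50")
  }
  p
}

#' Plot a protocol result
#'
#' Intensity sweeps are shown as condition-mean metric curves over amplitude
#' scale; cue combination and gain inversion as trial-averaged time courses;
#' two-cue shift as preference index against the single-cue accuracy
#' difference.
#'
#' @param object A `protocol_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.protocol_result <- function(object, ...) {
  th <- ggplot2::theme_minimal()
  switch(
    object$protocol,
    intensity_sweep = {
      long <- tidyr::pivot_longer(
        object$conditions[c("A_scale", "accuracy", "width", "amplitude", "notch")],
        -"A_scale", names_to = "metric", values_to = "value")
      ggplot2::ggplot(long, ggplot2::aes(.data$A_scale, .data$value)) +
        ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
        ggplot2::facet_wrap(~metric, scales = "free_y") +
        ggplot2::labs(x = "ER amplitude scale", y = NULL) + th
    },
    cue_combination = {
      ggplot2::ggplot(object$timecourse,
                      ggplot2::aes(.data$t_exp, .data$accuracy)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "experiment time (s)", y = "HD encoding accuracy") + th
    },
    gain_inversion = {
      ggplot2::ggplot(object$timecourse,
                      ggplot2::aes(.data$t_exp, .data$norm_accuracy,
                                   colour = factor(.data$A_scale))) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "experiment time (s)",
                      y = "normalized HD encoding accuracy",
                      colour = "ER scale") + th
    },
    two_cue_shift = {
      d <- dplyr::mutate(object$trials,
                         acc_diff = .data$acc_cue1 - .data$acc_cue2)
      ggplot2::ggplot(d, ggplot2::aes(.data$acc_diff, .data$index_all)) +
        ggplot2::geom_point() +
        ggplot2::labs(x = "single-cue accuracy difference (visual - wind)",
                      y = "bump preference index") + th
    },
    stop("no plot defined for protocol ", object$protocol))
}

#' Plot a conflict-regression fit
#'
#' Observed conflict/offset-change pairs with the posterior-mean regression
#' line (wrapped).
#'
#' @param object A `conflict_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.conflict_fit <- function(object, ...) {
  est <- tidy(object)
  a <- est$estimate[est$term == "a"]; b <- est$estimate[est$term == "b"]
  grid <- tibble::tibble(theta = seq(-pi, pi, length.out = 200))
  grid$mu <- wrap_angle(a * grid$theta + b)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$theta, .data$phi)) +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = grid, ggplot2::aes(y = .data$mu),
                        size = 0.3, colour = "red") +
    ggplot2::labs(x = "conflict θ (rad)", y = "offset change φ (rad)") +
    ggplot2::theme_minimal()
}
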