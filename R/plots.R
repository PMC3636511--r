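#' Plot marker trajectories of a recording
#'
#' Quick-look facet plot of each coordinate over time for a subset of
#' markers.
#'
#' @param object A `bow_recording`.
#' @param markers Markers to show (default: the bow markers and wrist).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bow_recording <- function(object,
                                   markers = c("bow_tip", "bow_mid", "wrist"),
                                   ...) {
  dat <- tidyr::pivot_longer(
    object[object$marker %in% markers, ],
    cols = c("x", "y", "z"), names_to = "coord", values_to = "mm"
  )
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$time, y = .data$mm, colour = .data$marker)
  ) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~coord, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "position (mm)") +
    ggplot2::theme_minimal()
}

#' Plot bow velocity and acceleration around reversals
#'
#' Time-locks bow kinematics to each retained reversal and overlays the
#' per-event traces, the classic view in which expert reversals show a flat
#' velocity plateau with a single sharp acceleration impulse and novice
#' reversals a bell-shaped velocity with distributed acceleration.
#'
#' @param bk A [bow_kinematics()].
#' @param events Retained events.
#' @param window Half-width of the plotted window, s.
#' @return A ggplot object.
#' @export
plot_reversal_profiles <- function(bk, events, window = 0.375) {
  dat <- purrr::map_dfr(seq_len(nrow(events)), function(i) {
    idx <- which(abs(bk$time - events$t_rev[i]) <= window)
    tibble::tibble(
      event = events$event[i], direction = events$direction[i],
      t = bk$time[idx] - events$t_rev[i],
      velocity = bk$velocity[idx], acceleration = bk$acceleration[idx]
    )
  })
  dat <- tidyr::pivot_longer(dat, c("velocity", "acceleration"),
    names_to = "signal", values_to = "value"
  )
  ggplot2::ggplot(
    dat,
    ggplot2::aes(
      x = .data$t, y = .data$value,
      group = .data$event
    )
  ) +
    ggplot2::geom_line(alpha = 0.4, na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_grid(signal ~ direction, scales = "free_y") +
    ggplot2::labs(x = "time relative to bow reversal (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot coordination features along the kinematic chain
#'
#' Group means (with standard errors) of a per-marker or per-joint feature
#' against chain position, the standard display of proximal-to-distal
#' gradients.
#'
#' @param features Subject-level feature table (e.g. `subject_markers` from
#'   [run_pipeline()]), with columns `group`, `direction`, a chain factor
#'   and a value column.
#' @param value Name of the value column.
#' @param chain Name of the chain factor column (`"marker"` or `"joint"`).
#' @return A ggplot object.
#' @export
plot_chain_profile <- function(features, value = "t_peak_acc",
                               chain = "marker") {
  dat <- dplyr::summarise(
    dplyr::group_by(
      features, .data$group, .data$direction, .data[[chain]]
    ),
    mean = mean(.data[[value]], na.rm = TRUE),
    se = sd(.data[[value]], na.rm = TRUE) /
      sqrt(sum(!is.na(.data[[value]]))),
    .groups = "drop"
  )
  ggplot2::ggplot(
    dat,
    ggplot2::aes(
      x = .data[[chain]], y = .data$mean, colour = .data$group,
      group = .data$group
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(
      ggplot2::aes(
        ymin = .data$mean - .data$se,
        ymax = .data$mean + .data$se
      )
    ) +
    ggplot2::facet_wrap(~direction) +
    ggplot2::labs(x = NULL, y = value) +
    ggplot2::theme_minimal()
}
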