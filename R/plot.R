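#' Plot a trajectory
#'
#' Draws the closed path with equal axis scaling and marks the starting
#' sample; the subtitle states the reference frame.
#'
#' @param object A trajectory ([as_trajectory()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.orbit_trajectory <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(colour = "#2c7fb8") +
    ggplot2::geom_point(data = df[1, ], colour = "#d95f02", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(subtitle = paste("frame:", trajectory_frame(object)),
                  x = "x (screen units)", y = "y (screen units)") +
    ggplot2::theme_minimal()
}

#' Plot the cue decomposition of a percept prediction
#'
#' Overlays the eye-centered path, the relative path and the weighted
#' perceived path for one stimulus and viewing condition, all centred on
#' the target orbit centre.
#'
#' @inheritParams predict_percept
#' @return A ggplot object.
#' @examples
#' plot_percept(make_preset("movie6"))
#' @export
plot_percept <- function(stimulus, condition = viewing_condition("fixate"),
                         k = NULL) {
  if (is.null(k)) k <- default_k(condition)
  fr <- percept_frames(stimulus, condition)
  ctr <- stimulus$target$center
  centred <- function(traj, label) {
    d <- displacements(traj)
    tibble::tibble(x = ctr[1] + d[, 1], y = ctr[2] + d[, 2], path = label)
  }
  per <- predict_percept(stimulus, condition, k)
  df <- dplyr::bind_rows(
    centred(fr$ec_target, "eye-centered"),
    if (!is.null(fr$relative)) centred(fr$relative, "relative"),
    tibble::tibble(x = per$x, y = per$y,
                   path = sprintf("perceived (k = %.2f)", k)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$path)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_manual(values = c("#000000", "#1b9e77", "#e7298a"),
                                 breaks = unique(df$path)) +
    ggplot2::labs(x = "x (screen units)", y = "y (screen units)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the fit objective of a cue-weight fit
#'
#' Shows the grid-search objective (mean squared distance between trace and
#' model) over `k`, the fitted optimum, and the bootstrap interval when
#' present.
#'
#' @param object An `orbit_fit` from [fit_k()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.orbit_fit <- function(object, ...) {
  df <- tibble::tibble(k = object$k_grid, mse = object$grid_mse)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$mse)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_vline(xintercept = object$k_hat, colour = "#d95f02") +
    ggplot2::labs(x = "cue weight k", y = "mean squared distance") +
    ggplot2::theme_minimal()
  if (!is.null(object$k_ci)) {
    p <- p + ggplot2::annotate("rect", xmin = object$k_ci[1],
                               xmax = object$k_ci[2], ymin = -Inf, ymax = Inf,
                               alpha = 0.15, fill = "#d95f02")
  }
  p
}
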