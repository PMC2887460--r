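#' Plot an availability sweep
#'
#' Availability (normalized peak test current) against the swept dimension;
#' duration sweeps use a logarithmic x axis, matching how onset and
#' recovery curves are read.
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, ...) {
  field <- attr(object, "sweep_field") %||% "sweep_value"
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data$sweep_value, y = .data$relative_current,
    colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = if (field == "duration") "duration (s)" else "voltage (mV)",
      y = "relative current",
      title = attr(object, "protocol"),
      subtitle = attr(object, "drug")) +
    ggplot2::theme_minimal()
  if (field == "duration") p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot the effectiveness plane
#'
#' nSOD in the recovery protocol against nSOD in the slow-inactivation
#' onset protocol, with the convex-hull regions of the fast- and
#' slow-preferring drug families.
#'
#' @param object An `nsod_plane`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nsod_plane <- function(object, ...) {
  pts <- object$points
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$nsod_onset,
                                         y = .data$nsod_recovery))
  for (fam in names(object$regions)) {
    hull <- as.data.frame(object$regions[[fam]])
    hull$family <- fam
    p <- p + ggplot2::geom_polygon(
      data = hull, ggplot2::aes(fill = .data$family), alpha = 0.2)
  }
  if (!all(is.na(pts$family))) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$family))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "nSOD (onset, SInact_t)",
                  y = "nSOD (recovery, Rec_t)") +
    ggplot2::theme_minimal()
}

#' Plot a state-occupancy trajectory
#'
#' @param object A `trajectory`.
#' @param states Which state columns to draw (default: total conducting
#'   occupancy only).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trajectory <- function(object, states = NULL, ...) {
  df <- tibble(time = object$times, conducting = object$conducting)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time,
                                        y = .data$conducting)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "conducting occupancy") +
    ggplot2::theme_minimal()
  if (!is.null(states)) {
    occ <- as.data.frame(object$occupancies[, states, drop = FALSE])
    occ$time <- object$times
    long <- tidyr::pivot_longer(occ, -"time", names_to = "state",
                                values_to = "occupancy")
    p <- ggplot2::ggplot(long, ggplot2::aes(
      x = .data$time, y = .data$occupancy, colour = .data$state)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (s)", y = "occupancy") +
      ggplot2::theme_minimal()
  }
  p
}
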