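#' Plot a trajectory
#'
#' Concentration of every gene over time on a log10 axis.
#'
#' @param object A `kin_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kin_trajectory
#' @export
autoplot.kin_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"time",
    names_to = "gene", values_to = "conc"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$time, y = .data$conc, colour = .data$gene
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "time step", y = "concentration (nM)", colour = NULL,
      subtitle = if (is_aborted(object)) {
        paste0("aborted at step ", attr(object, "abort_time"))
      }
    ) +
    ggplot2::theme_minimal()
}

#' Plot the solution map
#'
#' The deterministic deviation `DD` against the stochastic deviation `DS`
#' for every parameter set, coloured by the four-quadrant class; sentinel
#' rows collapse onto the top-right corner.
#'
#' @param scan A `kin_scan`.
#' @param alpha Point transparency.
#' @return A ggplot object.
#' @export
plot_solution_map <- function(scan, alpha = 0.3) {
  if (!inherits(scan, "kin_scan")) abort("Expected a `kin_scan`.")
  ggplot2::ggplot(as_tibble(scan), ggplot2::aes(
    x = .data$DD, y = .data$DS, colour = .data$class
  )) +
    ggplot2::geom_point(alpha = alpha, size = 0.6) +
    ggplot2::labs(
      x = "deterministic deviation DD", y = "stochastic deviation DS",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_solution_map
#' @param object A `kin_scan`.
#' @param ... Unused.
#' @method autoplot kin_scan
#' @export
autoplot.kin_scan <- function(object, ...) plot_solution_map(object, ...)

#' Plot a handbook overview
#'
#' Motif performance score against rank, sized by member count; motifs below
#' the size cut are hollow.
#'
#' @param object A `kin_handbook`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kin_handbook
#' @export
autoplot.kin_handbook <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(
    x = .data$rank, y = .data$score, size = .data$size,
    shape = .data$sub_threshold
  )) +
    ggplot2::geom_point() +
    ggplot2::scale_shape_manual(
      values = c(`FALSE` = 16, `TRUE` = 1), guide = "none"
    ) +
    ggplot2::labs(
      x = "handbook rank", y = "mean DD + mean DS",
      size = "members"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
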