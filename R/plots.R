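#' @import ggplot2
NULL

#' Plot a free-energy profile
#'
#' @param object A `free_energy_profile` from [pmf()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.free_energy_profile <- function(object, ...) {
  d <- filter(as_tibble(object), !.data$empty)
  ggplot(d, aes(x = .data$bin_center, y = .data$dg)) +
    geom_ribbon(
      aes(ymin = .data$dg - .data$se, ymax = .data$dg + .data$se),
      alpha = 0.25, fill = "steelblue"
    ) +
    geom_line(color = "steelblue") +
    labs(
      x = expression(Delta * D[Z] ~ (ring(A))),
      y = expression(Delta * G[B] ~ (kcal / mol))
    ) +
    theme_minimal()
}

#' Plot a membrane curvature profile
#'
#' @param object A `curvature_profile` from [curvature_profile()].
#' @param ... Unused.
#' @return A ggplot with height (top) and curvature (bottom) panels.
#' @export
autoplot.curvature_profile <- function(object, ...) {
  d <- as_tibble(object) |>
    tidyr::pivot_longer(c("h_smooth", "curvature"),
      names_to = "panel", values_to = "value"
    ) |>
    mutate(panel = ifelse(.data$panel == "h_smooth", "h(X) [A]", "C(X) [1/nm]"))
  fp <- attr(object, "footprint")
  ggplot(d, aes(x = .data$x, y = .data$value)) +
    geom_line(color = "firebrick") +
    annotate("rect",
      xmin = fp[1], xmax = fp[2], ymin = -Inf, ymax = Inf, alpha = 0.1
    ) +
    facet_wrap(~panel, ncol = 1, scales = "free_y") +
    labs(x = "X (A)", y = NULL) +
    theme_minimal()
}

#' Plot a lateral MSD curve
#'
#' @param object An `msd_result` from [lateral_msd()].
#' @param ... Unused.
#' @return A ggplot of MSD vs lag time.
#' @export
autoplot.msd_result <- function(object, ...) {
  d <- as_tibble(object)
  p <- ggplot(d, aes(x = .data$lag, y = .data$msd))
  if ("x_bin" %in% names(d)) {
    p <- p + geom_line(aes(group = .data$x_bin, color = factor(.data$x_bin)))
  } else {
    p <- p + geom_pointrange(aes(
      ymin = .data$msd - .data$se, ymax = .data$msd + .data$se
    ), color = "darkgreen")
  }
  p + labs(x = "lag (ns)", y = expression("<" * Delta * r^2 * "> (" * ring(A)^2 * ")"),
    color = "X bin") +
    theme_minimal()
}

#' Plot a protein-lipid interaction-energy map
#'
#' @param object An `energy_map` from [interaction_map()].
#' @param ... Unused.
#' @return A ggplot heat map.
#' @export
autoplot.energy_map <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$x, y = .data$y, fill = .data$energy)) +
    geom_tile() +
    scale_fill_gradient2(low = "darkred", mid = "white", high = "darkblue") +
    labs(x = "X (A)", y = "Y (A)", fill = "E (kcal/mol)") +
    coord_equal() +
    theme_minimal()
}

#' Plot binding-geometry time series
#'
#' @param orientation Tibble from [orientation_series()].
#' @return A ggplot faceted over the observables.
#' @export
plot_orientation <- function(orientation) {
  d <- tidyr::pivot_longer(
    orientation, c("theta", "delta_d_z", "gap_z", "min_pair_distance"),
    names_to = "observable", values_to = "value"
  )
  ggplot(d, aes(x = .data$time, y = .data$value)) +
    geom_line(color = "steelblue") +
    facet_wrap(~observable, scales = "free_y") +
    labs(x = "time (ns)", y = NULL) +
    theme_minimal()
}
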