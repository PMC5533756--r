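#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a free-energy profile
#'
#' @param x A `free_energy_profile` from [pmf()].
#' @param ... Unused.
#' @return Tibble `bin_center`, `dg`, `se`, `n_samples`, `empty`.
#' @export
tidy.free_energy_profile <- function(x, ...) {
  as_tibble(x)[, c("bin_center", "dg", "se", "n_samples", "empty")]
}

#' One-row summary of a free-energy profile
#'
#' Reports the binding depth as the free energy at the farthest sampled bin
#' relative to the global minimum (which is anchored at zero), with the
#' minimum's location and solver diagnostics.
#'
#' @param x A `free_energy_profile` from [pmf()].
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.free_energy_profile <- function(x, ...) {
  fit <- attr(x, "fit")
  ok <- !x$empty
  far <- which(ok)[which.max(x$bin_center[ok])]
  tibble(
    n_bins = nrow(x),
    n_empty = sum(x$empty),
    n_windows = nrow(fit$f),
    n_samples = length(fit$x),
    iterations = fit$iterations,
    min_location = x$bin_center[which.min(x$dg)],
    dg_at_far_bin = x$dg[far],
    binding_dg = -x$dg[far]
  )
}

#' Tidy a quasi-harmonic mode spectrum
#'
#' @param x A `mode_spectrum` from [covariance_pca()].
#' @param ... Unused.
#' @return Tibble `mode`, `lambda`, `omega_rad_ps`.
#' @export
tidy.mode_spectrum <- function(x, ...) as_tibble(x)

#' One-row summary of a mode spectrum
#'
#' @param x A `mode_spectrum` from [covariance_pca()].
#' @param ... Unused.
#' @return One-row tibble with mode counts and the entropy at the spectrum's
#'   temperature.
#' @export
glance.mode_spectrum <- function(x, ...) {
  tibble(
    n_modes = nrow(x),
    n_dropped = attr(x, "n_dropped"),
    rank_deficient = attr(x, "rank_deficient"),
    temperature = attr(x, "temperature"),
    s_internal = internal_entropy(x, attr(x, "temperature"))
  )
}

#' Tidy thermodynamic-cycle components
#'
#' @param x A `cycle_components` from [assemble_cycle()].
#' @param ... Unused.
#' @return The component tibble.
#' @export
tidy.cycle_components <- function(x, ...) as_tibble(x)

#' One-row summary of a thermodynamic cycle
#'
#' @param x A `cycle_components` from [assemble_cycle()].
#' @param ... Unused.
#' @return One-row tibble with the binding free energy (at the grid point
#'   with the smallest reaction coordinate if a series) and the
#'   solvation/interaction-energy correlation when available.
#' @export
glance.cycle_components <- function(x, ...) {
  row <- if ("delta_d_z" %in% names(x)) which.min(abs(x$delta_d_z)) else 1
  tibble(
    dg_b = x$dg_b[row],
    de_protein = x$de_protein[row],
    minus_tds = x$minus_tds[row],
    ddmu = x$ddmu[row],
    cor_ddmu_de_int = attr(x, "cor_ddmu_de_int") %||% NA_real_
  )
}
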