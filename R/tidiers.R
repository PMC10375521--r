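# broom-style tidiers and ggplot2 autoplot methods.

#' Tidy a Monte Carlo trajectory (energy trace)
#'
#' @param x A `g4_trajectory`.
#' @param ... Unused.
#' @return The energy trace as a tibble: `sweep`, `energy` (u0 units),
#'   `phase`.
#' @method tidy g4_trajectory
#' @export
tidy.g4_trajectory <- function(x, ...) x$energy_trace

#' One-row summary of a Monte Carlo trajectory
#'
#' @param x A `g4_trajectory`.
#' @param ... Unused.
#' @return A tibble with particle count, box edge, T*, K, mean production
#'   energy per particle, the energy-route `M`, acceptance rates and the
#'   stationarity flag.
#' @method glance g4_trajectory
#' @export
glance.g4_trajectory <- function(x, ...) {
  n <- nrow(x$state$centers)
  prod_e <- x$energy_trace$energy[x$energy_trace$phase == "prod"]
  eps <- mean(prod_e) / n
  tibble::tibble(
    n_particles = n, box = x$state$box, K = x$state$shape$K,
    Tstar = x$state$params$Tstar, mode = x$state$mode,
    energy_per_particle = eps,
    M_energy = if (abs(eps) < 1) M_from_energy(eps) else NA_real_,
    acc_translation = x$acceptance[["translation"]],
    acc_rotation = x$acceptance[["rotation"]],
    n_snapshots = length(x$snapshots),
    stationary = energy_stationary(x)$stationary
  )
}

#' Tidy chain statistics (the chain-length histogram)
#'
#' @param x A `g4_chain_stats`.
#' @param ... Unused.
#' @return Histogram tibble: `length`, `count`, `fraction` and the
#'   step-growth theory density `nu_theory` at the cluster-route `M`.
#' @method tidy g4_chain_stats
#' @export
tidy.g4_chain_stats <- function(x, ...) {
  h <- x$histogram
  nu <- chain_length_distribution_theory(h$length, x$rho, x$M_cluster)
  dplyr::mutate(h,
                fraction = .data$count / sum(.data$count),
                nu_theory = nu)
}

#' One-row summary of chain statistics
#'
#' @param x A `g4_chain_stats`.
#' @param ... Unused.
#' @return Tibble with the three M estimates, dispersity, mean adjacent
#'   angle, mean gyration radius and branch-node count.
#' @method glance g4_chain_stats
#' @export
glance.g4_chain_stats <- function(x, ...) {
  tibble::tibble(
    M_energy = x$M_energy, M_cluster = x$M_cluster, M_fit = x$M_fit,
    dispersity = x$dispersity, mean_adjacent_angle = x$mean_adjacent_angle,
    Rg_mean = x$Rg_mean, branch_nodes = x$branch_nodes,
    n_particles = x$n_particles, n_snapshots = x$n_snapshots
  )
}

#' Tidy a (K, T*) grid fit
#'
#' @param x A `g4_fit_grid`.
#' @param ... Unused.
#' @return The RSS landscape tibble: `K`, `Tstar`, `rss`, `scale`, `M`,
#'   `stationary`.
#' @method tidy g4_fit_grid
#' @export
tidy.g4_fit_grid <- function(x, ...) x$grid

#' One-row summary of a (K, T*) grid fit
#'
#' @param x A `g4_fit_grid`.
#' @param ... Unused.
#' @return The best-point report: `K`, `Tstar`, `rss`, `M`, `dispersity`
#'   and stacking thermodynamics.
#' @method glance g4_fit_grid
#' @export
glance.g4_fit_grid <- function(x, ...) x$best

#' Plot a scattering curve (log-log)
#'
#' @param object A [scattering_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scattering_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$Q, y = .data$I)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(Q ~ (nm^-1)), y = "I(Q) (a.u.)")
  if ("sigma" %in% names(object)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(.data$I - .data$sigma, .Machine$double.xmin),
                   ymax = .data$I + .data$sigma),
      alpha = 0.3)
  }
  p
}

#' Plot the energy trace of a trajectory
#'
#' @param object A `g4_trajectory`.
#' @param ... Unused.
#' @return A ggplot of energy per sweep, colored by phase.
#' @export
autoplot.g4_trajectory <- function(object, ...) {
  ggplot2::ggplot(object$energy_trace,
                  ggplot2::aes(x = .data$sweep, y = .data$energy,
                               color = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "MC sweep", y = expression(E / u[0]), color = NULL)
}

#' Plot a chain-length histogram with the step-growth theory curve
#'
#' @param object A `g4_chain_stats`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.g4_chain_stats <- function(object, ...) {
  d <- tidy(object)
  d$nu_frac <- d$nu_theory * d$length / sum(d$nu_theory * d$length)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count / sum(.data$count)),
                      fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$nu_frac), color = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "chain length l", y = "fraction of chains")
}

#' Plot the RSS landscape of a grid fit
#'
#' @param object A `g4_fit_grid`.
#' @param ... Unused.
#' @return A ggplot tile map of log10 RSS over (K, T*), best point marked.
#' @export
autoplot.g4_fit_grid <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$K, y = .data$Tstar,
                               fill = log10(.data$rss))) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = object$best, fill = NA, shape = 4, size = 3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "K", y = "T*", fill = expression(log[10] ~ RSS))
}
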