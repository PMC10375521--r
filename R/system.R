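# System construction and the canonical Monte Carlo driver.

#' Number density from molar concentration
#'
#' `rho = N_av * C`, returned in nm^-3 for `C` in mol/L.
#'
#' @param concentration Molar concentration, mol/L.
#' @return Number density in nm^-3.
#' @export
number_density <- function(concentration) {
  stopifnot(concentration > 0)
  AVOGADRO_NM3 * concentration
}

#' Cubic box edge for `n` units at a molar concentration
#'
#' @param n Number of units (particles in monomer mode, trimers in trimer
#'   mode).
#' @inheritParams number_density
#' @return Box edge length in nm such that `n / box^3 = N_av * C`.
#' @examples
#' box_edge(6292, 0.6e-3)  # ~259.3 nm
#' @export
box_edge <- function(n, concentration) (n / number_density(concentration))^(1 / 3)

# covalent topology bookkeeping for trimer systems: particles are stored in
# consecutive triplets (bottom, middle, top); each tether joins the + face of
# the lower particle to the - face of the upper one.
trimer_topology <- function(n_trimers) {
  base <- 3 * (seq_len(n_trimers) - 1)
  cov_partner <- matrix(-1L, nrow = 3 * n_trimers, ncol = 2)
  cov_face <- matrix(0L, nrow = 3 * n_trimers, ncol = 2)
  for (t in base) {
    cov_partner[t + 1, 1] <- t + 1L; cov_face[t + 1, 1] <- 1L   # bottom + <-> middle -
    cov_partner[t + 2, 1] <- t + 0L; cov_face[t + 2, 1] <- -1L
    cov_partner[t + 2, 2] <- t + 2L; cov_face[t + 2, 2] <- 1L   # middle + <-> top -
    cov_partner[t + 3, 1] <- t + 1L; cov_face[t + 3, 1] <- -1L
  }
  list(partner = cov_partner, face = cov_face,
       group = rep(seq_len(n_trimers), each = 3))
}

# site masks: monomer particles carry sites on both faces; trimer terminal
# bases have no stacking site on their outward faces
site_masks <- function(n_particles, mode) {
  if (mode == "monomer") {
    list(plus = rep(1L, n_particles), minus = rep(1L, n_particles))
  } else {
    pos <- (seq_len(n_particles) - 1L) %% 3L  # 0 bottom, 1 middle, 2 top
    list(plus = as.integer(pos != 2L), minus = as.integer(pos != 0L))
  }
}

#' Initialize a system on an orthorhombic lattice
#'
#' Places `n` hard cylinders (monomer mode) or `n` covalently tethered
#' trimers (trimer mode) on a cubic lattice inside a periodic box whose
#' volume realizes the requested number density `N_av * C`.  All axes start
#' along +z; trimer triplets are stacked coaxially with their tethers
#' satisfied.  Construction is deterministic; `seed` is stored and used by
#' [run_mc()].
#'
#' @param n Number of particles (monomer mode) or trimers (trimer mode).
#' @param shape A [cylinder_shape()].
#' @param concentration Molar concentration of units (particles or trimers),
#'   mol/L.  Alternatively give `mg_per_ml` together with `molar_mass`.
#' @param Tstar Reduced temperature `kB*T/u0`.
#' @param mode `"monomer"` or `"trimer"`.
#' @param params Optional [interaction_params()]; defaults to the mode's
#'   standard ranges.
#' @param seed Integer seed stored in the state and used by [run_mc()].
#' @param mg_per_ml Mass concentration in mg/mL (trimer experiments are
#'   specified this way); converted using `molar_mass`.
#' @param molar_mass Molar mass in g/mol used with `mg_per_ml`; the default
#'   22600 g/mol corresponds to the Tel72 d(TTAGGG)12 sequence.
#'
#' @return An object of class `g4_system`: fields `centers`, `axes`, `ex`
#'   (n_particles x 3 matrices), `box` (nm), `shape`, `params`, `mode`,
#'   `topology` (trimer mode), `energy` (units of u0), `rng_seed`.
#' @examples
#' sys <- init_lattice(64, cylinder_shape(1), concentration = 0.6e-3, Tstar = 0.1)
#' sys$box
#' @export
init_lattice <- function(n, shape = cylinder_shape(), concentration = NULL,
                         Tstar = 0.1, mode = c("monomer", "trimer"),
                         params = NULL, seed = NULL,
                         mg_per_ml = NULL, molar_mass = 22600) {
  mode <- match.arg(mode)
  stopifnot(n >= 1)
  if (is.null(concentration)) {
    if (is.null(mg_per_ml)) stop("give `concentration` (mol/L) or `mg_per_ml`")
    concentration <- mg_per_ml / molar_mass  # mg/mL over g/mol = mol/L
  }
  if (is.null(params)) params <- interaction_params(Tstar, mode = mode, D0 = shape$D0)
  if (params$mode != mode) stop("`params` mode does not match `mode`")
  params$Tstar <- Tstar

  box <- box_edge(n, concentration)
  m <- ceiling(n^(1 / 3))
  spacing <- box / m

  if (mode == "monomer") {
    need <- max(shape$D, shape$L) * (1 + 1e-9)
    if (spacing <= need) {
      stop(sprintf("density too high for lattice placement: spacing %.3g nm <= %.3g nm",
                   spacing, need), call. = FALSE)
    }
    idx <- seq_len(n) - 1
    centers <- cbind((idx %% m), ((idx %/% m) %% m), (idx %/% (m * m))) * spacing +
      spacing / 2
    axes <- matrix(rep(c(0, 0, 1), each = n), ncol = 3)
    ex <- matrix(rep(c(1, 0, 0), each = n), ncol = 3)
    topo <- NULL
  } else {
    s <- shape$L + 0.45 * params$delta_cov  # intra-trimer axial spacing
    need_z <- (2 * s + shape$L) * (1 + 1e-9)
    need_xy <- shape$D * (1 + 1e-9)
    if (spacing <= max(need_z, need_xy)) {
      stop(sprintf("density too high for trimer lattice placement: spacing %.3g nm",
                   spacing), call. = FALSE)
    }
    idx <- seq_len(n) - 1
    base <- cbind((idx %% m), ((idx %/% m) %% m), (idx %/% (m * m))) * spacing +
      spacing / 2
    centers <- matrix(0, 3 * n, 3)
    for (t in seq_len(n)) {
      for (k in 1:3) {
        centers[3 * (t - 1) + k, ] <- base[t, ] + c(0, 0, (k - 2) * s)
      }
    }
    centers <- centers %% box
    axes <- matrix(rep(c(0, 0, 1), each = 3 * n), ncol = 3)
    ex <- matrix(rep(c(1, 0, 0), each = 3 * n), ncol = 3)
    topo <- trimer_topology(n)
  }

  masks <- site_masks(nrow(centers), mode)
  state <- structure(
    list(centers = centers, axes = axes, ex = ex, box = box, shape = shape,
         params = params, mode = mode, topology = topo,
         site_plus = masks$plus, site_minus = masks$minus,
         concentration = concentration, energy = NA_real_, rng_seed = seed),
    class = "g4_system"
  )
  state$energy <- system_energy(state)
  state
}

#' @export
print.g4_system <- function(x, ...) {
  cat(sprintf("<g4_system> %d %s particles in a %.4g nm box (K = %.3g, T* = %.3g)\n",
              nrow(x$centers),
              if (x$mode == "trimer") "trimer-linked" else "monomer",
              x$box, x$shape$K, x$params$Tstar))
  cat(sprintf("  energy: %.6g u0\n", x$energy))
  invisible(x)
}

#' Recompute the total square-well energy of a system (all pairs)
#'
#' @param state A `g4_system` or a snapshot from [run_mc()] together with the
#'   originating state's metadata.
#' @return Total energy in units of `u0`.
#' @export
system_energy <- function(state) {
  total_energy_cpp(state$centers, state$axes, state$site_plus, state$site_minus,
                   state$shape$D, state$shape$L, state$params$delta, state$box)
}

#' List overlapping particle pairs (validation)
#'
#' Exhaustive all-pairs overlap scan; a valid hard-core configuration returns
#' zero rows.
#'
#' @param state A `g4_system`.
#' @return Two-column integer matrix of overlapping (i, j) pairs (1-based).
#' @export
overlapping_pairs <- function(state) {
  overlapping_pairs_cpp(state$centers, state$axes, state$shape$D, state$shape$L,
                        state$box)
}

#' Monte Carlo schedule
#'
#' A "sweep" is `N` attempted single-particle moves (50% translations, 50%
#' rotations).  Move amplitudes may be auto-tuned during equilibration
#' (targeting acceptance between 0.3 and 0.5) and are frozen during
#' production, preserving detailed balance where samples are taken.
#'
#' @param n_equil Equilibration sweeps.
#' @param n_prod Production sweeps.
#' @param sample_every Sampling cadence in sweeps.
#' @param max_translation Initial maximum translation amplitude, nm.
#' @param max_rotation Initial maximum rotation angle, radians.
#' @param tune Auto-tune amplitudes during equilibration?
#' @return An object of class `mc_schedule`.
#' @export
mc_schedule <- function(n_equil = 20000, n_prod = 20000, sample_every = 200,
                        max_translation = 1.0, max_rotation = 0.5, tune = TRUE) {
  stopifnot(n_equil >= 0, n_prod >= 1, sample_every >= 1,
            max_translation > 0, max_rotation > 0)
  structure(list(n_equil = as.integer(n_equil), n_prod = as.integer(n_prod),
                 sample_every = as.integer(sample_every),
                 max_translation = max_translation, max_rotation = max_rotation,
                 tune = isTRUE(tune)),
            class = "mc_schedule")
}

#' Run canonical (NVT*) Metropolis Monte Carlo
#'
#' Samples hard-cylinder configurations with square-well stacking attraction
#' by single-particle translation/rotation moves under periodic boundary
#' conditions.  Moves creating a hard-core overlap (or, in trimer mode,
#' stretching a covalent tether beyond its cutoff) are rejected; otherwise
#' Metropolis acceptance `min(1, exp(-dE / T*))` applies with energies in
#' units of `u0`.
#'
#' @param state A `g4_system` from [init_lattice()].
#' @param schedule An [mc_schedule()].
#' @param seed Optional integer seed; defaults to the seed stored in `state`.
#'   Runs are reproducible given the seed.
#' @return An object of class `g4_trajectory`: `snapshots` (list of sampled
#'   configurations), `energy_trace` (tibble: sweep, energy, phase),
#'   `state` (final `g4_system` with updated coordinates and cached energy),
#'   `acceptance`, `schedule`.
#' @export
run_mc <- function(state, schedule = mc_schedule(), seed = NULL) {
  stopifnot(inherits(state, "g4_system"), inherits(schedule, "mc_schedule"))
  seed <- if (is.null(seed)) state$rng_seed else seed
  topo <- state$topology
  trimer <- state$mode == "trimer"
  cov_partner <- if (trimer) topo$partner else matrix(-1L, nrow(state$centers), 2)
  cov_face <- if (trimer) topo$face else matrix(0L, nrow(state$centers), 2)
  res <- with_seed(seed, run_mc_cpp(
    state$centers, state$axes, state$ex,
    state$site_plus, state$site_minus,
    cov_partner, cov_face,
    state$shape$D, state$shape$L, state$shape$D0,
    state$params$delta,
    if (trimer) state$params$delta_cov else 0,
    state$params$Tstar, state$box,
    schedule$n_equil, schedule$n_prod, schedule$sample_every,
    schedule$max_translation, schedule$max_rotation, schedule$tune, trimer
  ))
  final <- state
  final$centers <- res$centers
  final$axes <- res$axes
  final$ex <- res$ex
  final$energy <- res$energy
  n_sw <- schedule$n_equil + schedule$n_prod
  trace <- tibble::tibble(
    sweep = seq_len(n_sw),
    energy = as.numeric(res$energy_trace),
    phase = rep(c("equil", "prod"), c(schedule$n_equil, schedule$n_prod))
  )
  structure(
    list(snapshots = res$snapshots, energy_trace = trace, state = final,
         acceptance = c(translation = res$acc_translation,
                        rotation = res$acc_rotation),
         amplitudes = c(translation = res$max_translation,
                        rotation = res$max_rotation),
         schedule = schedule, seed = seed),
    class = "g4_trajectory"
  )
}

#' @export
print.g4_trajectory <- function(x, ...) {
  cat(sprintf("<g4_trajectory> %d snapshots of %d particles (box %.4g nm)\n",
              length(x$snapshots), nrow(x$state$centers), x$state$box))
  cat(sprintf("  acceptance: translation %.2f, rotation %.2f; final E = %.5g u0\n",
              x$acceptance[["translation"]], x$acceptance[["rotation"]],
              x$state$energy))
  invisible(x)
}

#' Attempt a single Metropolis move on one particle
#'
#' A reference-path single move, mainly useful for inspecting the acceptance
#' rule: proposes a translation (uniform in a cube of side
#' `2 * max_translation`) or a rotation about a random axis, rejects overlap
#' creation outright, and otherwise applies Metropolis acceptance.
#'
#' @param state A `g4_system`.
#' @param i Particle index (1-based).
#' @param move `"translation"` or `"rotation"`.
#' @param max_translation,max_rotation Move amplitudes (nm, radians).
#' @return A list with the (possibly updated) `state`, `accepted`, and the
#'   energy change `dE` of the proposal.
#' @export
attempt_move <- function(state, i, move = c("translation", "rotation"),
                         max_translation = 1.0, max_rotation = 0.5) {
  stopifnot(inherits(state, "g4_system"), i >= 1, i <= nrow(state$centers))
  move <- match.arg(move)
  new <- state
  if (move == "translation") {
    new$centers[i, ] <- (state$centers[i, ] + runif(3, -1, 1) * max_translation) %% state$box
  } else {
    k <- rnorm(3)
    k <- k / sqrt(sum(k^2))
    ang <- runif(1, -1, 1) * max_rotation
    rot <- function(v) {
      v * cos(ang) + pracma_cross(k, v) * sin(ang) + k * sum(k * v) * (1 - cos(ang))
    }
    new$axes[i, ] <- rot(state$axes[i, ])
    new$axes[i, ] <- new$axes[i, ] / sqrt(sum(new$axes[i, ]^2))
    e <- rot(state$ex[i, ])
    e <- e - sum(e * new$axes[i, ]) * new$axes[i, ]
    new$ex[i, ] <- e / sqrt(sum(e^2))
  }
  # covalent tethers
  if (state$mode == "trimer") {
    topo <- state$topology
    for (t in 1:2) {
      j <- topo$partner[i, t]
      if (j < 0) next
      jj <- j + 1L
      fi <- topo$face[i, t]
      tj <- if (topo$partner[jj, 1] == i - 1L) 1L else 2L
      fj <- topo$face[jj, tj]
      si <- rim_site_r(new, i, fi)
      sj <- rim_site_r(new, jj, fj)
      d <- si - sj
      d <- d - state$box * round(d / state$box)
      if (sum(d^2) > state$params$delta_cov^2) {
        return(list(state = state, accepted = FALSE, dE = NA_real_))
      }
    }
  }
  # overlap with any other particle
  n <- nrow(state$centers)
  others <- setdiff(seq_len(n), i)
  if (length(others) > 0) {
    dc <- sweep(new$centers[others, , drop = FALSE], 2, new$centers[i, ])
    dc <- dc - state$box * round(dc / state$box)
    ov <- cylinders_overlap_cpp(
      matrix(rep(0, 3 * length(others)), ncol = 3),
      matrix(rep(new$axes[i, ], length(others)), ncol = 3, byrow = TRUE),
      dc, new$axes[others, , drop = FALSE],
      rep(state$shape$D, length(others)), rep(state$shape$L, length(others)),
      rep(state$shape$D, length(others)), rep(state$shape$L, length(others))
    )
    if (any(ov)) return(list(state = state, accepted = FALSE, dE = Inf))
  }
  e_old <- state$energy
  new$energy <- system_energy(new)
  dE <- new$energy - e_old
  if (dE <= 0 || runif(1) < exp(-dE / state$params$Tstar)) {
    list(state = new, accepted = TRUE, dE = dE)
  } else {
    list(state = state, accepted = FALSE, dE = dE)
  }
}

rim_site_r <- function(state, i, face) {
  state$centers[i, ] + face * (state$shape$L / 2) * state$axes[i, ] +
    (state$shape$D / 2) * state$ex[i, ]
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Test stationarity of the energy trace
#'
#' Scaled-down runs are judged equilibrated when the potential energy shows
#' no monotone trend over the examined window.  The window is aggregated
#' into block means (so that sweep-to-sweep autocorrelation does not inflate
#' the trend signal) and a Mann-Kendall test is applied to the blocks; only
#' a decisive monotone drift is flagged.
#'
#' @param traj A `g4_trajectory`.
#' @param phase Which part of the trace to examine (default: the second half
#'   of equilibration, falling back to production when `n_equil = 0`).
#' @param n_blocks Number of block means used in the trend test.
#' @param p_cutoff Significance level below which a trend is declared.
#' @param min_drift Practical-relevance threshold: a statistically
#'   significant trend only counts as non-stationary when the fitted drift
#'   across the window also exceeds this fraction of the mean energy
#'   magnitude (small residual drifts cannot move the derived observables
#'   beyond their sampling error).
#' @return A list with `stationary` (logical), `p_value`, `tau` and the
#'   relative `drift` across the window.
#' @export
energy_stationary <- function(traj, phase = c("equil", "prod"), n_blocks = 12,
                              p_cutoff = 0.005, min_drift = 0.1) {
  phase <- match.arg(phase)
  tr <- traj$energy_trace
  if (phase == "equil" && any(tr$phase == "equil")) {
    tr <- tr[tr$phase == "equil", ]
    tr <- tr[tr$sweep > max(tr$sweep) / 2, ]
  } else {
    tr <- tr[tr$phase == "prod", ]
  }
  grp <- rep(seq_len(n_blocks),
             each = ceiling(nrow(tr) / n_blocks))[seq_len(nrow(tr))]
  e <- as.numeric(tapply(tr$energy, grp, mean))
  if (length(unique(e)) < 3) {
    return(list(stationary = TRUE, p_value = 1, tau = 0, drift = 0))
  }
  ct <- suppressWarnings(cor.test(seq_along(e), e, method = "kendall"))
  fit <- lm(e ~ seq_along(e))
  drift <- abs(unname(coef(fit)[2])) * (length(e) - 1) /
    max(abs(mean(e)), .Machine$double.eps)
  list(stationary = ct$p.value > p_cutoff || drift < min_drift,
       p_value = ct$p.value, tau = unname(ct$estimate), drift = drift)
}
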