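# Multimer observables: bond graph, chain statistics, angles, trimer bond
# classification, gyration radii and the center-of-mass structure factor.

# snapshots as a uniform list; accepts a trajectory or a single system state
as_snapshots <- function(x) {
  if (inherits(x, "g4_trajectory")) {
    list(snaps = x$snapshots, state = x$state)
  } else if (inherits(x, "g4_system")) {
    list(snaps = list(list(centers = x$centers, axes = x$axes, ex = x$ex,
                           energy = x$energy, sweep = NA_integer_)),
         state = x)
  } else {
    stop("expected a `g4_trajectory` or `g4_system`")
  }
}

# stacking-site coordinates for a snapshot: matrix with particle index and
# face attribute
snapshot_sites <- function(centers, axes, site_plus, site_minus, shape) {
  off <- site_offset(shape)
  plus <- which(site_plus == 1L)
  minus <- which(site_minus == 1L)
  sites <- rbind(centers[plus, , drop = FALSE] + off * axes[plus, , drop = FALSE],
                 centers[minus, , drop = FALSE] - off * axes[minus, , drop = FALSE])
  list(sites = sites, particle = c(plus, minus),
       face = rep(c(1L, -1L), c(length(plus), length(minus))))
}

#' Stacking bond graph of one configuration
#'
#' Two particles are bonded iff any pair of their stacking sites lies within
#' the square-well range `delta` (strict inequality, minimum image).
#'
#' @param centers,axes `N x 3` coordinate matrices (a snapshot).
#' @param state The originating `g4_system` (supplies shape, ranges, box and
#'   site masks).
#' @return A tibble of bonded pairs `(i, j)` with `i < j`.
#' @export
bond_graph <- function(centers, axes, state) {
  ss <- snapshot_sites(centers, axes, state$site_plus, state$site_minus,
                       state$shape)
  s <- ss$sites
  ns <- nrow(s)
  delta2 <- state$params$delta^2
  box <- state$box
  pairs <- NULL
  if (ns >= 2) {
    # all site pairs, vectorized per coordinate with minimum image
    dx <- outer(s[, 1], s[, 1], "-"); dx <- dx - box * round(dx / box)
    dy <- outer(s[, 2], s[, 2], "-"); dy <- dy - box * round(dy / box)
    dz <- outer(s[, 3], s[, 3], "-"); dz <- dz - box * round(dz / box)
    d2 <- dx * dx + dy * dy + dz * dz
    hit <- which(d2 < delta2, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    if (nrow(hit) > 0) {
      pi <- ss$particle[hit[, 1]]
      pj <- ss$particle[hit[, 2]]
      keep <- pi != pj
      pairs <- unique(cbind(pmin(pi[keep], pj[keep]), pmax(pi[keep], pj[keep])))
    }
  }
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(tibble::tibble(i = integer(), j = integer()))
  }
  tibble::tibble(i = as.integer(pairs[, 1]), j = as.integer(pairs[, 2]))
}

# connected components of the bond graph; returns membership vector
chain_membership <- function(edges, n) {
  if (nrow(edges) == 0) return(seq_len(n))
  g <- igraph::graph_from_edgelist(as.matrix(edges[, c("i", "j")]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::components(g)$membership
}

#' Theoretical chain-length distribution of step-growth assembly
#'
#' The equilibrium (Flory, exponential) number density of chains of length
#' `l`: `nu(l) = rho * M^-(l+1) * (M - 1)^(l-1)`, with the `0^0 = 1`
#' convention so that `M = 1` gives a pure monomer solution.  The identity
#' `sum_l l * nu(l) = rho` (monomer conservation) holds for every `M >= 1`.
#'
#' @param l Chain length(s), integer >= 1.
#' @param rho Number density of units (any unit; sets the scale).
#' @param M Average chain length, >= 1.
#' @return `nu(l)`, same length as `l`.
#' @export
chain_length_distribution_theory <- function(l, rho, M) {
  stopifnot(all(l >= 1), rho > 0)
  if (M < 1) stop("`M` must be >= 1", call. = FALSE)
  if (M == 1) return(ifelse(l == 1, rho, 0))
  rho * M^(-(l + 1)) * (M - 1)^(l - 1)
}

#' Average chain length from the mean energy per particle
#'
#' With `b = |epsilon| / u0` the number of stacking bonds per particle, the
#' average number of stacked units is `M = (1 - b)^-1` (each bond joins two
#' chains; `N_chains = N - N_bonds`).
#'
#' @param mean_energy_per_particle Mean square-well energy per particle in
#'   units of `u0` (a non-positive number, or its magnitude).
#' @return `M >= 1`.
#' @examples
#' M_from_energy(0)     # 1: no bonds
#' M_from_energy(-0.5)  # 2: every particle in a dimer
#' @export
M_from_energy <- function(mean_energy_per_particle) {
  b <- abs(mean_energy_per_particle)
  if (any(b >= 1)) {
    stop("bonds per particle >= 1: chain reading of M undefined (M = Inf)",
         call. = FALSE)
  }
  1 / (1 - b)
}

#' Dispersity of a step-growth chain-length distribution
#'
#' `D = 2 - 1/M`, the mass-average over number-average molecular weight
#' ratio of an exponential (most probable) distribution.
#'
#' @param M Average chain length, >= 1.
#' @return Dispersity in `[1, 2)`.
#' @examples
#' dispersity(1.66)  # 1.40
#' dispersity(1.13)  # 1.12
#' @export
dispersity <- function(M) {
  stopifnot(all(M >= 1))
  2 - 1 / M
}

# geometric (Flory) fit of a chain-length histogram by log-linear regression:
# log nu(l) is linear in l with slope log((M-1)/M)
fit_M_histogram <- function(lengths, counts) {
  keep <- counts > 0 & lengths >= 1
  if (sum(keep) < 2) return(NA_real_)
  fit <- lm(log(counts[keep]) ~ lengths[keep])
  ratio <- exp(unname(coef(fit)[2]))
  if (!is.finite(ratio) || ratio <= 0 || ratio >= 1) return(NA_real_)
  1 / (1 - ratio)
}

#' Chain statistics of a trajectory
#'
#' Builds the stacking bond graph of every sampled configuration and pools:
#' the chain-length histogram, the average chain length by three routes
#' (mean energy, `N / N_chains`, and a fit of the exponential length
#' distribution), the dispersity, nematic angles between bonded neighbours,
#' and per-chain gyration radii.  Branch nodes (degree > 2), which the
#' hard-core geometry makes rare, are counted and reported rather than
#' dropped.
#'
#' @param x A `g4_trajectory` (or a single `g4_system`).
#' @return An object of class `g4_chain_stats`; see [glance.g4_chain_stats()]
#'   for the one-row summary.
#' @export
chain_statistics <- function(x) {
  sn <- as_snapshots(x)
  state <- sn$state
  n <- nrow(state$centers)
  hist_tbl <- list()
  n_chains <- numeric(length(sn$snaps))
  energies <- numeric(length(sn$snaps))
  branch_nodes <- 0L
  angles <- list()
  rgs <- list()
  for (k in seq_along(sn$snaps)) {
    s <- sn$snaps[[k]]
    edges <- bond_graph(s$centers, s$axes, state)
    memb <- chain_membership(edges, n)
    sizes <- tabulate(memb)
    sizes <- sizes[sizes > 0]
    n_chains[k] <- length(sizes)
    energies[k] <- if (is.na(s$energy)) system_energy(state) else s$energy
    deg <- tabulate(c(edges$i, edges$j), nbins = n)
    branch_nodes <- branch_nodes + sum(deg > 2)
    hist_tbl[[k]] <- tibble::tibble(snapshot = k, length = sizes)
    if (nrow(edges) > 0) {
      cosang <- abs(rowSums(s$axes[edges$i, , drop = FALSE] *
                              s$axes[edges$j, , drop = FALSE]))
      angles[[k]] <- acos(pmin(1, cosang)) * 180 / pi
    }
    rgs[[k]] <- chain_rg(s$centers, memb, state)
  }
  hist_all <- dplyr::bind_rows(hist_tbl)
  histogram <- hist_all %>%
    dplyr::count(.data$length, name = "count") %>%
    dplyr::arrange(.data$length)
  # per-snapshot averages, then pooled
  M_cluster <- mean(n / n_chains)
  M_energy <- M_from_energy(mean(energies) / n)
  M_fit <- fit_M_histogram(histogram$length, histogram$count)
  structure(
    list(histogram = histogram, n_particles = n, n_snapshots = length(sn$snaps),
         M_energy = M_energy, M_cluster = M_cluster, M_fit = M_fit,
         dispersity = dispersity(M_cluster),
         mean_adjacent_angle = if (length(angles)) mean(unlist(angles)) else NA_real_,
         angles = unlist(angles),
         Rg = unlist(rgs), Rg_mean = mean(unlist(rgs)),
         branch_nodes = branch_nodes,
         rho = n / state$box^3),
    class = "g4_chain_stats"
  )
}

#' @export
print.g4_chain_stats <- function(x, ...) {
  cat(sprintf("<g4_chain_stats> %d particles, %d snapshots\n",
              x$n_particles, x$n_snapshots))
  cat(sprintf("  M (energy / cluster / fit): %.3f / %.3f / %s\n",
              x$M_energy, x$M_cluster,
              if (is.na(x$M_fit)) "NA" else sprintf("%.3f", x$M_fit)))
  cat(sprintf("  dispersity %.3f, mean adjacent angle %s, <Rg> %.3f nm\n",
              x$dispersity,
              if (is.na(x$mean_adjacent_angle)) "NA"
              else sprintf("%.1f deg", x$mean_adjacent_angle),
              x$Rg_mean))
  invisible(x)
}

# per-chain gyration radius with uniform-cylinder mass distribution
# (parallel-axis composition of the single-cylinder Rg)
chain_rg <- function(centers, memb, state) {
  rg_cyl2 <- state$shape$L^2 / 12 + state$shape$D^2 / 8
  box <- state$box
  vapply(split(seq_len(nrow(centers)), memb), function(idx) {
    cc <- centers[idx, , drop = FALSE]
    # unwrap chain members around the first one (chains are short vs box/2)
    ref <- cc[1, ]
    d <- sweep(cc, 2, ref)
    d <- d - box * round(d / box)
    cm <- colMeans(d)
    sqrt(rg_cyl2 + mean(rowSums(sweep(d, 2, cm)^2)))
  }, numeric(1))
}

#' Gyration radii of multimers in a trajectory
#'
#' Chains are connected components of the stacking bond graph (monomer mode)
#' or the covalent triplets (trimer mode).  Each particle contributes the
#' mass distribution of a uniform cylinder, composed by the parallel-axis
#' theorem: `Rg^2 = L^2/12 + D^2/8 + <|r_i - r_cm|^2>`.
#'
#' @param x A `g4_trajectory` or `g4_system`.
#' @return A tibble with one row per chain per snapshot: `snapshot`,
#'   `length`, `Rg` (nm).
#' @export
gyration_radius <- function(x) {
  sn <- as_snapshots(x)
  state <- sn$state
  n <- nrow(state$centers)
  out <- lapply(seq_along(sn$snaps), function(k) {
    s <- sn$snaps[[k]]
    memb <- if (state$mode == "trimer") state$topology$group
            else chain_membership(bond_graph(s$centers, s$axes, state), n)
    rg <- chain_rg(s$centers, memb, state)
    tibble::tibble(snapshot = k, length = as.integer(table(memb)),
                   Rg = unname(rg))
  })
  dplyr::bind_rows(out)
}

#' Angles between adjacent cylinders
#'
#' In monomer mode adjacency means a stacking bond and angles use the
#' nematic (axis-sign-free) convention `acos(|u_i . u_j|)`.  In trimer mode
#' adjacency is the covalent topology (HC1-HC2 and HC2-HC3) and axes are
#' compared as consistently oriented along the chain.
#'
#' @param x A `g4_trajectory` or `g4_system`.
#' @return A tibble: `snapshot`, `i`, `j`, `angle` (degrees); trimer mode
#'   additionally `trimer` and `pair` (1 for HC1-HC2, 2 for HC2-HC3).
#' @export
adjacent_angles <- function(x) {
  sn <- as_snapshots(x)
  state <- sn$state
  out <- lapply(seq_along(sn$snaps), function(k) {
    s <- sn$snaps[[k]]
    if (state$mode == "trimer") {
      grp <- state$topology$group
      nt <- max(grp)
      b <- 3 * (seq_len(nt) - 1)
      i <- c(b + 1, b + 2)
      j <- c(b + 2, b + 3)
      cosang <- rowSums(s$axes[i, , drop = FALSE] * s$axes[j, , drop = FALSE])
      tibble::tibble(snapshot = k, i = i, j = j,
                     trimer = rep(seq_len(nt), 2),
                     pair = rep(c(1L, 2L), each = nt),
                     angle = acos(pmax(-1, pmin(1, cosang))) * 180 / pi)
    } else {
      edges <- bond_graph(s$centers, s$axes, state)
      if (nrow(edges) == 0) {
        return(tibble::tibble(snapshot = integer(), i = integer(),
                              j = integer(), angle = numeric()))
      }
      cosang <- abs(rowSums(s$axes[edges$i, , drop = FALSE] *
                              s$axes[edges$j, , drop = FALSE]))
      tibble::tibble(snapshot = k, i = edges$i, j = edges$j,
                     angle = acos(pmin(1, cosang)) * 180 / pi)
    }
  })
  dplyr::bind_rows(out)
}

#' Classify trimers by their number of stacking bonds
#'
#' For every sampled trimer, counts the stacking bonds (site pairs within the
#' square-well range) between its consecutive cylinders -- 0, 1 or 2 -- and
#' returns the population fractions together with the bond-count-conditioned
#' joint distribution of the two inter-cylinder angles (theta1, theta2).
#' Trimers with 0 or 1 bond are "beads-on-a-string" configurations.
#'
#' @param x A trimer-mode `g4_trajectory`.
#' @return A list of class `g4_trimer_classes`: `fractions` (tibble with
#'   `n_bonds`, `count`, `fraction`; fractions sum to 1), `angles` (tibble
#'   with `theta1`, `theta2`, `n_bonds` per trimer per snapshot).
#' @export
trimer_bond_classification <- function(x) {
  sn <- as_snapshots(x)
  state <- sn$state
  if (state$mode != "trimer") stop("trimer-mode trajectory required")
  grp <- state$topology$group
  nt <- max(grp)
  delta2 <- state$params$delta^2
  box <- state$box
  off <- site_offset(state$shape)
  rows <- lapply(seq_along(sn$snaps), function(k) {
    s <- sn$snaps[[k]]
    b <- 3 * (seq_len(nt) - 1)
    bonded_pair <- function(lo, hi) {
      # stacking bond between consecutive HCs: any stacking-site pair within
      # delta; lower particle's + site faces upper particle's - site, but all
      # existing site combinations are checked
      site_list <- function(i) {
        res <- list()
        if (state$site_plus[i] == 1L) {
          res <- c(res, list(s$centers[i, ] + off * s$axes[i, ]))
        }
        if (state$site_minus[i] == 1L) {
          res <- c(res, list(s$centers[i, ] - off * s$axes[i, ]))
        }
        res
      }
      for (si in site_list(lo)) {
        for (sj in site_list(hi)) {
          d <- si - sj
          d <- d - box * round(d / box)
          if (sum(d^2) < delta2) return(TRUE)
        }
      }
      FALSE
    }
    b12 <- vapply(b, function(t) bonded_pair(t + 1, t + 2), logical(1))
    b23 <- vapply(b, function(t) bonded_pair(t + 2, t + 3), logical(1))
    cos1 <- rowSums(s$axes[b + 1, , drop = FALSE] * s$axes[b + 2, , drop = FALSE])
    cos2 <- rowSums(s$axes[b + 2, , drop = FALSE] * s$axes[b + 3, , drop = FALSE])
    tibble::tibble(
      snapshot = k, trimer = seq_len(nt),
      n_bonds = as.integer(b12) + as.integer(b23),
      theta1 = acos(pmax(-1, pmin(1, cos1))) * 180 / pi,
      theta2 = acos(pmax(-1, pmin(1, cos2))) * 180 / pi
    )
  })
  angles <- dplyr::bind_rows(rows)
  fractions <- tibble::tibble(n_bonds = 0:2) %>%
    dplyr::left_join(dplyr::count(angles, .data$n_bonds, name = "count"),
                     by = "n_bonds") %>%
    dplyr::mutate(count = ifelse(is.na(.data$count), 0L, .data$count),
                  fraction = .data$count / sum(.data$count))
  structure(list(fractions = fractions, angles = angles),
            class = "g4_trimer_classes")
}

#' @export
print.g4_trimer_classes <- function(x, ...) {
  f <- x$fractions$fraction
  cat(sprintf("<g4_trimer_classes> f0 = %.3f, f1 = %.3f, f2 = %.3f (%d samples)\n",
              f[1], f[2], f[3], sum(x$fractions$count)))
  invisible(x)
}

#' Center-of-mass static structure factor
#'
#' Orientationally averaged `S(Q)` from particle centers via the pair
#' distance histogram (minimum image, binned to half the box edge) with the
#' analytic ideal-gas background subtracted, so that an uncorrelated system
#' gives `S(Q) = 1` up to sampling noise:
#' `S(Q) = 1 + (2/N) sum_bins (counts - n_ideal(r)) sinc(Q r)`.
#'
#' @param x A `g4_trajectory` or `g4_system`.
#' @param Q Scattering vector grid, nm^-1 (positive).
#' @param dr Histogram bin width, nm.
#' @param subtract_ideal Subtract the uniform background (default `TRUE`;
#'   turn off to obtain the raw truncated Debye sum).
#' @return A tibble: `Q`, `S`.
#' @export
structure_factor <- function(x, Q, dr = 0.02, subtract_ideal = TRUE) {
  stopifnot(all(Q > 0), all(diff(Q) > 0))
  sn <- as_snapshots(x)
  state <- sn$state
  n <- nrow(state$centers)
  box <- state$box
  rmax <- box / 2
  nb <- ceiling(rmax / dr)
  counts <- numeric(nb)
  for (s in sn$snaps) {
    counts <- counts + pair_histogram_cpp(s$centers, box, dr, rmax, TRUE)
  }
  counts <- counts / length(sn$snaps)
  r_mid <- (seq_len(nb) - 0.5) * dr
  ideal <- if (subtract_ideal) {
    # exact shell volume for r <= box/2 under the minimum-image metric
    (n * (n - 1) / 2) * 4 * pi * r_mid^2 * dr / box^3
  } else {
    0
  }
  eff <- counts - ideal
  S <- vapply(Q, function(q) {
    1 + (2 / n) * sum(eff * sin(q * r_mid) / (q * r_mid))
  }, numeric(1))
  tibble::tibble(Q = Q, S = S)
}

#' Locate the structure-factor stacking peak above a threshold Q
#'
#' Returns the position of the dominant maximum of `S(Q)` at `Q > q_min`.
#' The curve is lightly smoothed (running mean) first, so that sampling
#' noise does not masquerade as a local maximum.
#'
#' @param sq A tibble from [structure_factor()].
#' @param q_min Search above this Q (excludes the low-Q compressibility
#'   rise).
#' @param smooth Width (in grid points, odd) of the running-mean smoother.
#' @return The peak position in nm^-1.
#' @export
sq_first_peak <- function(sq, q_min = 1, smooth = 5) {
  idx <- which(sq$Q > q_min)
  s <- sq$S[idx]
  if (smooth > 1 && length(s) > smooth) {
    sm <- as.numeric(stats::filter(s, rep(1 / smooth, smooth), sides = 2))
    pad <- is.na(sm)
    sm[pad] <- s[pad]
    s <- sm
  }
  sq$Q[idx[which.max(s)]]
}
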