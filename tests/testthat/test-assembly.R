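# Chain statistics, angles, gyration radii and the structure factor.

test_that("step-growth length distribution obeys its identities", {
  # monodisperse limit (0^0 = 1 convention)
  expect_equal(chain_length_distribution_theory(1, rho = 2, M = 1), 2)
  expect_equal(chain_length_distribution_theory(2:6, rho = 2, M = 1), rep(0, 5))
  # monomer conservation: sum_l l * nu(l) = rho, for a spread of M
  l <- 1:400
  for (M in c(1.02, 1.5, 2, 3.31, 6)) {
    expect_equal(sum(l * chain_length_distribution_theory(l, rho = 0.7, M = M)),
                 0.7, tolerance = 1e-10)
  }
  # direct values at M = 2, rho = 1: nu(l) = 2^-(l+1)
  expect_equal(chain_length_distribution_theory(1:4, rho = 1, M = 2),
               2^-(2:5), tolerance = 1e-12)
  expect_error(chain_length_distribution_theory(1, rho = 1, M = 0.9))
})

test_that("M from energy follows the bonds-per-particle bookkeeping", {
  expect_equal(M_from_energy(0), 1)
  expect_equal(M_from_energy(-0.5), 2)   # all dimers: N/2 bonds
  expect_equal(M_from_energy(0.5), 2)    # magnitude convention
  expect_equal(M_from_energy(-2 / 3), 3) # all trimer chains
  expect_error(M_from_energy(-1), "undefined")
})

test_that("dispersity is 2 - 1/M", {
  expect_equal(dispersity(1), 1)
  expect_equal(round(dispersity(1.66), 2), 1.40)
  expect_equal(round(dispersity(1.13), 2), 1.12)
  expect_true(all(dispersity(c(1, 1.5, 3, 100)) >= 1))
  expect_true(all(dispersity(c(1, 1.5, 3, 100)) < 2))
})

# a hand-built dilute configuration with one bonded dimer and one free
# particle; bond graph and statistics are fully predictable
make_dimer_state <- function(angle_deg = 0) {
  shp <- cylinder_shape(1)
  C <- 3 / (6.02214076e23 * 1e-24) / 60^3
  sys <- init_lattice(3, shp, concentration = C, Tstar = 0.1)
  off <- shp$L / 2 + 0.15 * shp$D / 2
  a <- angle_deg * pi / 180
  sys$centers[1, ] <- c(10, 10, 10)
  sys$axes[1, ] <- c(0, 0, 1)
  # particle 2 stacked on 1: its minus site near 1's plus site
  sys$axes[2, ] <- c(sin(a), 0, cos(a))
  sys$centers[2, ] <- c(10, 10, 10) + c(0, 0, off + 0.2) +
    off * sys$axes[2, ]
  sys$centers[3, ] <- c(40, 40, 40)
  sys$axes[3, ] <- c(0, 0, 1)
  sys$energy <- system_energy(sys)
  sys
}

test_that("bond graph and chain statistics resolve a known dimer", {
  sys <- make_dimer_state()
  expect_equal(sys$energy, -1)
  edges <- bond_graph(sys$centers, sys$axes, sys)
  expect_equal(nrow(edges), 1)
  expect_equal(c(edges$i, edges$j), c(1L, 2L))
  cs <- chain_statistics(sys)
  expect_equal(sum(cs$histogram$length * cs$histogram$count), 3)
  expect_equal(cs$M_cluster, 1.5)
  expect_equal(cs$M_energy, M_from_energy(-1 / 3))
  expect_equal(cs$branch_nodes, 0L)
})

test_that("adjacent angles use the nematic convention in monomer mode", {
  expect_equal(adjacent_angles(make_dimer_state(0))$angle, 0, tolerance = 1e-7)
  expect_equal(adjacent_angles(make_dimer_state(20))$angle, 20, tolerance = 1e-7)
  # the nematic convention folds obtuse axes back below 90 degrees
  expect_equal(adjacent_angles(make_dimer_state(168))$angle, 12, tolerance = 1e-6)
})

test_that("gyration radii match closed forms for cylinders and stacked dimers", {
  shp <- cylinder_shape(1)
  rg1 <- sqrt(shp$L^2 / 12 + shp$D^2 / 8)
  expect_equal(rg1, 1.168, tolerance = 1e-3)
  # point-sampled oracle for the single-cylinder Rg
  set.seed(91)
  p <- cylinder_particle(c(0, 0, 0), c(0, 0, 1), shp)
  pts <- sample_in_cylinder(p, 4e5)
  rg_mc <- sqrt(mean(rowSums(sweep(pts, 2, colMeans(pts))^2)))
  expect_equal(rg_mc, rg1, tolerance = 5e-3)
  # coaxial contact dimer via parallel-axis composition
  sys <- make_dimer_state(0)
  rg <- gyration_radius(sys)
  s <- sqrt(sum((sys$centers[2, ] - sys$centers[1, ])^2))
  expect_equal(sort(rg$Rg), sort(c(rg1, sqrt(rg1^2 + s^2 / 4))),
               tolerance = 1e-9)
  # two-cylinder point-sampled oracle
  p2 <- cylinder_particle(sys$centers[2, ] - sys$centers[1, ], sys$axes[2, ], shp)
  pts2 <- rbind(sample_in_cylinder(p, 2e5), sample_in_cylinder(p2, 2e5))
  rg2_mc <- sqrt(mean(rowSums(sweep(pts2, 2, colMeans(pts2))^2)))
  expect_equal(max(rg$Rg), rg2_mc, tolerance = 1e-2)
})

test_that("structure factor is flat for an ideal gas and exact for a fixed pair", {
  # random uncorrelated centers
  set.seed(92)
  C <- 400 / (6.02214076e23 * 1e-24) / 60^3
  sys <- init_lattice(400, cylinder_shape(1), concentration = C, Tstar = 0.1)
  sys$centers <- matrix(runif(1200, 0, sys$box), ncol = 3)
  Q <- seq(0.3, 4, by = 0.1)
  sq <- structure_factor(sys, Q)
  expect_lt(max(abs(sq$S - 1)), 0.35)      # pointwise sampling noise
  expect_lt(abs(mean(sq$S) - 1), 0.05)
  # two particles at fixed separation d: S(Q) = 1 + sinc(Q d)
  C2 <- 2 / (6.02214076e23 * 1e-24) / 80^3
  sys2 <- init_lattice(2, cylinder_shape(1), concentration = C2, Tstar = 0.1)
  d <- 3.3
  sys2$centers[1, ] <- c(40, 40, 40)
  sys2$centers[2, ] <- c(40, 40, 40 + d)
  sq2 <- structure_factor(sys2, Q, dr = 0.005)
  expect_equal(sq2$S, 1 + sin(Q * d) / (Q * d), tolerance = 0.02)
})

test_that("monomer conservation holds in every sampled snapshot", {
  traj <- cached_run("warm_small", function() {
    sys <- init_lattice(96, cylinder_shape(1.1), concentration = 1.2e-3,
                        Tstar = 0.1, seed = 31)
    run_mc(sys, mc_schedule(n_equil = 4000, n_prod = 8000, sample_every = 400))
  })
  st <- traj$state
  for (s in traj$snapshots) {
    memb <- g4stack:::chain_membership(bond_graph(s$centers, s$axes, st),
                                       nrow(st$centers))
    expect_identical(sum(tabulate(memb)), nrow(st$centers))
  }
})

test_that("trimer bond fractions sum to one and angles are consistent", {
  traj <- get_trimer_run()
  tc <- trimer_bond_classification(traj)
  expect_equal(sum(tc$fractions$fraction), 1, tolerance = 1e-12)
  expect_identical(sum(tc$fractions$count), nrow(tc$angles))
  expect_true(all(tc$angles$theta1 >= 0 & tc$angles$theta1 <= 180))
  # oriented (not nematic) angles in trimer mode can exceed 90 degrees
  ang <- adjacent_angles(traj)
  expect_true(any(ang$angle > 90))
})
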