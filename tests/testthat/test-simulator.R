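# Lattice initialization, the Metropolis kernel and its invariants.

test_that("lattice initialization realizes the requested number density", {
  # closed-form density arithmetic: box^3 = n / (N_av * C)
  expect_equal(box_edge(6292, 0.6e-3),
               (6292 / (6.02214076e23 * 0.6e-3 * 1e-24))^(1 / 3),
               tolerance = 1e-12)
  sys <- init_lattice(64, cylinder_shape(1), concentration = 0.6e-3,
                      Tstar = 0.1)
  expect_equal(64 / sys$box^3, 6.02214076e23 * 0.6e-3 * 1e-24,
               tolerance = 1e-12)
  # overfull lattice is rejected explicitly
  expect_error(init_lattice(64, cylinder_shape(1), concentration = 2,
                            Tstar = 0.1), "density too high")
})

test_that("dilute lattice starts unbonded and overlap-free", {
  C <- 8 / (6.02214076e23 * 1e-24) / 100^3  # 8 particles in a 100 nm box
  sys <- init_lattice(8, cylinder_shape(1), concentration = C, Tstar = 0.1)
  expect_equal(sys$box, 100, tolerance = 1e-9)
  expect_equal(sys$energy, 0)
  expect_identical(nrow(overlapping_pairs(sys)), 0L)
  # 2 x 2 x 2 arrangement: nearest-neighbor distance is half the box
  d <- as.matrix(dist(sys$centers))
  expect_equal(min(d[d > 0]), 50, tolerance = 1e-9)
})

test_that("trimer lattice satisfies covalent constraints at initialization", {
  sys <- init_lattice(2, cylinder_shape(1.4), mg_per_ml = 10, Tstar = 0.195,
                      mode = "trimer")
  expect_identical(nrow(sys$centers), 6L)
  expect_identical(sys$topology$group, rep(1:2, each = 3))
  expect_identical(nrow(overlapping_pairs(sys)), 0L)
  # every tether within the covalent cutoff
  for (t in 0:1) {
    for (pair in list(c(1, 2), c(2, 3))) {
      i <- 3 * t + pair[1]
      j <- 3 * t + pair[2]
      si <- sys$centers[i, ] + (sys$shape$L / 2) * sys$axes[i, ] +
        (sys$shape$D / 2) * sys$ex[i, ]
      sj <- sys$centers[j, ] - (sys$shape$L / 2) * sys$axes[j, ] +
        (sys$shape$D / 2) * sys$ex[j, ]
      expect_lte(sqrt(sum((si - sj)^2)), sys$params$delta_cov)
    }
  }
  # terminal bases carry no outward stacking sites
  expect_identical(sys$site_plus, rep(c(1L, 1L, 0L), 2))
  expect_identical(sys$site_minus, rep(c(0L, 1L, 1L), 2))
})

test_that("runs are reproducible and the energy cache matches recomputation", {
  sys <- init_lattice(64, cylinder_shape(1), concentration = 0.6e-3,
                      Tstar = 0.1, seed = 21)
  sch <- mc_schedule(n_equil = 2000, n_prod = 2000, sample_every = 200)
  t1 <- run_mc(sys, sch)
  t2 <- run_mc(sys, sch)
  expect_identical(t1$state$centers, t2$state$centers)
  expect_identical(t1$energy_trace$energy, t2$energy_trace$energy)
  expect_equal(t1$state$energy, system_energy(t1$state), tolerance = 1e-9)
  for (s in t1$snapshots) {
    st <- t1$state
    st$centers <- s$centers
    st$axes <- s$axes
    expect_equal(s$energy, system_energy(st), tolerance = 1e-9)
  }
})

test_that("snapshots never contain overlapping pairs", {
  traj <- cached_run("warm_small", function() {
    sys <- init_lattice(96, cylinder_shape(1.1), concentration = 1.2e-3,
                        Tstar = 0.1, seed = 31)
    run_mc(sys, mc_schedule(n_equil = 4000, n_prod = 8000, sample_every = 400))
  })
  st <- traj$state
  for (s in traj$snapshots) {
    st$centers <- s$centers
    st$axes <- s$axes
    expect_identical(nrow(overlapping_pairs(st)), 0L)
  }
})

test_that("the athermal limit samples zero mean energy", {
  sys <- init_lattice(64, cylinder_shape(1), concentration = 0.6e-3,
                      Tstar = 10, seed = 41)
  traj <- run_mc(sys, mc_schedule(n_equil = 2000, n_prod = 4000,
                                  sample_every = 100))
  prod_e <- traj$energy_trace$energy[traj$energy_trace$phase == "prod"]
  expect_lt(abs(mean(prod_e)) / 64, 0.02)
})

test_that("single-move proposals respect hard-core rejection and free acceptance", {
  # isolated particle: every move is accepted (dE = 0, no overlap possible)
  C <- 1 / (6.02214076e23 * 1e-24) / 50^3
  sys1 <- init_lattice(1, cylinder_shape(1), concentration = C, Tstar = 0.1)
  set.seed(51)
  for (rep in 1:20) {
    res <- attempt_move(sys1, 1, sample(c("translation", "rotation"), 1))
    expect_true(res$accepted)
    expect_equal(res$dE, 0)
    sys1 <- res$state
  }
  # a translation forced into a neighbor creates overlap and is rejected
  shp <- cylinder_shape(1)
  sys2 <- init_lattice(8, shp, concentration = 8 / (6.02214076e23 * 1e-24) / 40^3,
                       Tstar = 0.1)
  # move particle 1 directly onto particle 2 with an enormous amplitude bias:
  # place them manually instead
  sys2$centers[1, ] <- sys2$centers[2, ] + c(0.3, 0, 0)
  expect_gt(nrow(overlapping_pairs(sys2)), 0)
  set.seed(52)
  res <- attempt_move(sys2, 1, "translation", max_translation = 1e-6)
  expect_false(res$accepted)  # still overlapping after a negligible move
})

test_that("average chain length is intensive in system size", {
  gl <- function(n, seed) {
    sys <- init_lattice(n, cylinder_shape(1), concentration = 1.2e-3,
                        Tstar = 0.11, seed = seed)
    traj <- run_mc(sys, mc_schedule(n_equil = 25000, n_prod = 25000,
                                    sample_every = 500))
    glance(traj)$M_energy
  }
  M_small <- gl(96, 71)
  M_large <- gl(384, 72)
  expect_gt(M_small, 1.02)  # the state point does multimerize
  expect_lt(abs(M_small - M_large) / M_large, 0.1)
})

test_that("trimer tethers never exceed the covalent cutoff in any snapshot", {
  traj <- get_trimer_run()
  st <- traj$state
  dcov <- st$params$delta_cov
  for (s in traj$snapshots[seq(1, length(traj$snapshots), by = 10)]) {
    for (t in seq(0, nrow(st$centers) - 3, by = 3)) {
      for (pair in list(c(1, 2), c(2, 3))) {
        i <- t + pair[1]
        j <- t + pair[2]
        si <- s$centers[i, ] + (st$shape$L / 2) * s$axes[i, ] +
          (st$shape$D / 2) * s$ex[i, ]
        sj <- s$centers[j, ] - (st$shape$L / 2) * s$axes[j, ] +
          (st$shape$D / 2) * s$ex[j, ]
        d <- si - sj
        d <- d - st$box * round(d / st$box)
        expect_lte(sqrt(sum(d^2)), dcov + 1e-9)
      }
    }
  }
})

test_that("equilibrated traces pass the stationarity check", {
  sys <- init_lattice(64, cylinder_shape(1), concentration = 0.5e-3,
                      Tstar = 0.14, seed = 81)
  traj <- run_mc(sys, mc_schedule(n_equil = 20000, n_prod = 10000,
                                  sample_every = 500))
  expect_true(energy_stationary(traj)$stationary)
})
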