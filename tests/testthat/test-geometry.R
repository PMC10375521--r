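# Hard-cylinder geometry: shapes, sites, overlap predicate, square well.

test_that("shape family preserves the diameter-length product", {
  for (K in seq(0.8, 1.8, by = 0.1)) {
    shp <- cylinder_shape(K)
    expect_gt(shp$D, 0)
    expect_gt(shp$L, 0)
    expect_equal(shp$D * shp$L, shp$D0 * shp$L0, tolerance = 1e-12)
  }
  expect_error(cylinder_shape(-1))
})

test_that("stacking sites sit on the axis at L/2 + 0.15 D/2", {
  p <- cylinder_particle(c(0, 0, 0), c(0, 0, 1))
  s <- stacking_site_positions(p)
  expect_equal(unname(s["plus", ]), c(0, 0, 1.709), tolerance = 1e-12)
  expect_equal(unname(s["minus", ]), c(0, 0, -1.709), tolerance = 1e-12)

  # translation equivariance
  p2 <- cylinder_particle(c(1, 2, 3), c(0, 0, 1))
  s2 <- stacking_site_positions(p2)
  expect_equal(unname(s2["plus", ]), c(1, 2, 3 + 1.709), tolerance = 1e-12)
  expect_equal(s2 - s, matrix(rep(c(1, 2, 3), each = 2), 2, 3,
                              dimnames = dimnames(s)), tolerance = 1e-12)

  # axis flip swaps the faces
  p3 <- cylinder_particle(c(0, 0, 0), c(0, 0, -1))
  s3 <- stacking_site_positions(p3)
  expect_equal(unname(s3["plus", ]), unname(s["minus", ]), tolerance = 1e-12)

  # non-unit axis is rejected
  expect_error(cylinder_particle(axis = c(0, 0, 2)), "unit")
})

test_that("site positions commute with rigid rotations", {
  set.seed(71)
  for (rep in 1:25) {
    R <- random_rotation_matrix()
    ctr <- rnorm(3)
    ax <- random_unit_vector()
    p <- cylinder_particle(ctr, ax, cylinder_shape(runif(1, 0.8, 1.8)))
    rotated <- cylinder_particle(as.numeric(R %*% ctr), as.numeric(R %*% ax),
                                 p$shape)
    s_then_rot <- stacking_site_positions(p) %*% t(R)
    rot_then_s <- stacking_site_positions(rotated)
    expect_equal(unname(rot_then_s), unname(s_then_rot), tolerance = 1e-10)
  }
})

test_that("covalent rim sites sit on the basal rim", {
  shp <- cylinder_shape(1.4)
  p <- cylinder_particle(c(0, 0, 0), c(0, 0, 1), shp, ex = c(1, 0, 0))
  cs <- covalent_site_positions(p)
  expect_equal(unname(cs["plus", ]), c(shp$D / 2, 0, shp$L / 2), tolerance = 1e-12)
  expect_equal(unname(cs["minus", ]), c(shp$D / 2, 0, -shp$L / 2), tolerance = 1e-12)
})

test_that("overlap predicate resolves coaxial, parallel and crossed cases", {
  shp <- cylinder_shape(1)  # D = 2.12, L = 3.10
  at <- function(ctr, ax = c(0, 0, 1)) cylinder_particle(ctr, ax, shp)
  a <- at(c(0, 0, 0))
  # coaxial: reduces to |dz| < L
  expect_true(cylinders_overlap(a, at(c(0, 0, 3.0))))
  expect_false(cylinders_overlap(a, at(c(0, 0, 3.2))))
  # parallel, same z: reduces to lateral distance < D
  expect_true(cylinders_overlap(a, at(c(2.0, 0, 0))))
  expect_false(cylinders_overlap(a, at(c(2.2, 0, 0))))
  # perpendicular crossed configuration
  b <- at(c(1.0, 0, 0), c(1, 0, 0))
  expect_true(cylinders_overlap(a, b))
  expect_true(overlap_sampling_certificate(a, b, 5000))
})

test_that("overlap predicate is symmetric and matches the sampling oracle", {
  set.seed(72)
  shp <- cylinder_shape(1)
  rc <- sqrt((shp$L / 2)^2 + (shp$D / 2)^2)
  n_false_negative <- 0
  for (rep in 1:300) {
    a <- cylinder_particle(c(0, 0, 0), random_unit_vector(), shp)
    # near-contact pairs: centers within the circumscribed-sphere reach
    b <- cylinder_particle(runif(1, 0.3, 2.1 * rc) * random_unit_vector(),
                           random_unit_vector(), shp)
    o_ab <- cylinders_overlap(a, b)
    expect_identical(o_ab, cylinders_overlap(b, a))
    # a sampled common point is an exact certificate of intersection
    if (!o_ab && overlap_sampling_certificate(a, b, 4000)) {
      n_false_negative <- n_false_negative + 1
    }
  }
  expect_identical(n_false_negative, 0)
  # guaranteed-separated pairs must never report overlap
  for (rep in 1:200) {
    a <- cylinder_particle(c(0, 0, 0), random_unit_vector(), shp)
    b <- cylinder_particle((2 * rc + runif(1, 1e-3, 3)) * random_unit_vector(),
                           random_unit_vector(), shp)
    expect_false(cylinders_overlap(a, b))
  }
})

test_that("square-well pair energy counts site pairs inside the open well", {
  shp <- cylinder_shape(1)
  prm <- interaction_params(Tstar = 0.1, mode = "monomer")
  expect_equal(prm$delta, 0.5)
  off <- shp$L / 2 + 0.15 * shp$D / 2
  a <- cylinder_particle(c(0, 0, 0), c(0, 0, 1), shp)
  # facing sites at distance r: centers separated by 2*off + r along z
  at_r <- function(r) cylinder_particle(c(0, 0, 2 * off + r), c(0, 0, 1), shp)
  expect_equal(sw_pair_energy(a, at_r(0.4), prm), -1)
  expect_equal(sw_pair_energy(a, at_r(0.6), prm), 0)
  # boundary r = delta is non-bonded (strict inequality)
  expect_equal(sw_pair_energy(a, at_r(0.5), prm), 0)
  # energy scales with u0
  expect_equal(sw_pair_energy(a, at_r(0.4), prm, u0 = 2.5), -2.5)
})

test_that("trimer-mode interaction defaults follow the reference diameter", {
  prm <- interaction_params(Tstar = 0.195, mode = "trimer", D0 = 2.12)
  expect_equal(prm$delta, 0.53)
  expect_equal(prm$delta_cov, 1.06)
})
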