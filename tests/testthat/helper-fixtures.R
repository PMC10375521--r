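# Shared fixtures and independent oracles for the test suite.

# uniform random point inside a cylinder particle's body (oracle helper)
sample_in_cylinder <- function(p, n) {
  R <- p$shape$D / 2
  L <- p$shape$L
  z <- runif(n, -L / 2, L / 2)
  r <- R * sqrt(runif(n))
  phi <- runif(n, 0, 2 * pi)
  u <- p$axis
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  sweep(outer(z, u) + outer(r * cos(phi), e1) + outer(r * sin(phi), e2),
        2, p$center, "+")
}

# exact membership test: is each point inside the cylinder?
points_in_cylinder <- function(pts, p) {
  d <- sweep(pts, 2, p$center)
  z <- as.numeric(d %*% p$axis)
  r2 <- rowSums(d^2) - z^2
  abs(z) <= p$shape$L / 2 & r2 <= (p$shape$D / 2)^2
}

# point-sampling overlap certificate: TRUE iff a sampled point of one body
# lies inside the other (a hit is an exact proof of intersection)
overlap_sampling_certificate <- function(a, b, n = 20000) {
  any(points_in_cylinder(sample_in_cylinder(a, n), b)) ||
    any(points_in_cylinder(sample_in_cylinder(b, n), a))
}

random_unit_vector <- function() {
  z <- rnorm(3)
  z / sqrt(sum(z^2))
}

random_rotation_matrix <- function() {
  k <- random_unit_vector()
  ang <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

# memoized expensive simulations shared across test blocks
.sim_cache <- new.env(parent = emptyenv())

cached_run <- function(key, fn) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- fn()
  .sim_cache[[key]]
}

# the multimeric self-assembly state point (K = 1, T* = 0.085, C = 0.6 mM)
get_multimer_run <- function() {
  cached_run("multimer", function() {
    sys <- init_lattice(256, cylinder_shape(1), concentration = 0.6e-3,
                        Tstar = 0.085, seed = 8)
    run_mc(sys, mc_schedule(n_equil = 220000, n_prod = 120000,
                            sample_every = 2000), seed = 8)
  })
}

# the concentrated multimeric state point used for the structure factor
get_dense_run <- function() {
  cached_run("dense", function() {
    sys <- init_lattice(256, cylinder_shape(1), concentration = 4.5e-3,
                        Tstar = 0.085, seed = 12)
    run_mc(sys, mc_schedule(n_equil = 100000, n_prod = 60000,
                            sample_every = 1000), seed = 12)
  })
}

# the trimer best-fit state point (K = 1.4, T* = 0.195, 10 mg/mL)
get_trimer_run <- function() {
  cached_run("trimer", function() {
    sys <- init_lattice(200, cylinder_shape(1.4), mg_per_ml = 10,
                        Tstar = 0.195, mode = "trimer", seed = 9)
    run_mc(sys, mc_schedule(n_equil = 12000, n_prod = 28000,
                            sample_every = 400), seed = 9)
  })
}
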