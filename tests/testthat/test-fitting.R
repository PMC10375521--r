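# SAXS file handling and the RSS machinery.

test_that("read_saxs_dat parses 2- and 3-column dialects with headers", {
  f3 <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# synthetic sample",
               "# Q I sigma",
               "0.10 100.0 1.0",
               "0.20 50.0 0.8",
               "1.40 12.5 0.4"), f3)
  c3 <- read_saxs_dat(f3)
  expect_s3_class(c3, "scattering_curve")
  expect_named(c3, c("Q", "I", "sigma"))
  expect_equal(c3$Q, c(0.1, 0.2, 1.4))

  f2 <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("Sample: no sigma column", "1.1 5.0", "2.2 2.0"), f2)
  c2 <- read_saxs_dat(f2)
  expect_false("sigma" %in% names(c2))
  expect_equal(c2$I, c(5, 2))
})

test_that("Q units are auto-detected and convertible", {
  fa <- withr::local_tempfile(fileext = ".dat")
  qa <- c(0.0044, 0.05, 0.2, 0.521)  # inverse Angstrom
  writeLines(sprintf("%g %g %g", qa, exp(-qa), 0.01), fa)
  curve <- read_saxs_dat(fa)
  expect_equal(curve$Q, qa * 10)      # now 0.044 .. 5.21 nm^-1
  expect_equal(attr(curve, "metadata")$unit_scale, 10)
  # explicit override keeps the values
  curve_nm <- read_saxs_dat(fa, unit = "nm")
  expect_equal(curve_nm$Q, qa)
})

test_that("malformed curves are rejected and negative intensities flagged", {
  fbad <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0.2 1.0", "0.1 2.0"), fbad)   # non-monotone Q
  expect_error(read_saxs_dat(fbad), "increasing")
  fempty <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# only a header", "no numbers here"), fempty)
  expect_error(read_saxs_dat(fempty), "no numeric data")
  fneg <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("1 1.0 0.1", "2 -0.2 0.1", "3 0.5 0.1"), fneg)
  cn <- read_saxs_dat(fneg)
  expect_identical(nrow(cn), 3L)   # retained ...
  expect_equal(attr(cn, "metadata")$n_nonpositive_I, 1)  # ... but counted
})

test_that("write/read round-trips a curve", {
  f <- withr::local_tempfile(fileext = ".dat")
  sc <- scattering_curve(c(1, 2, 3), c(9, 4, 1), sigma = c(0.3, 0.2, 0.1))
  write_saxs_dat(sc, f, header = "round trip")
  back <- read_saxs_dat(f)
  expect_equal(back$Q, sc$Q, tolerance = 1e-6)
  expect_equal(back$I, sc$I, tolerance = 1e-6)
  expect_equal(back$sigma, sc$sigma, tolerance = 1e-6)
})

test_that("match_and_rss recovers exact scale and background", {
  Q <- seq(0.1, 3, by = 0.05)
  Isim <- cylinder_form_factor(Q)
  sim <- scattering_curve(Q, Isim)
  exp_curve <- scattering_curve(Q, 7.5 * Isim + 0.3)
  m <- match_and_rss(sim, exp_curve, qrange = c(0.1, 3),
                     weighting = "linear", background = TRUE)
  expect_equal(m$scale, 7.5, tolerance = 1e-9)
  expect_equal(m$background, 0.3, tolerance = 1e-9)
  expect_equal(m$rss, 0, tolerance = 1e-12)
  # log weighting profiles a pure scale
  exp2 <- scattering_curve(Q, 42 * Isim)
  m2 <- match_and_rss(sim, exp2, qrange = c(0.1, 3), weighting = "log")
  expect_equal(m2$scale, 42, tolerance = 1e-9)
  expect_equal(m2$rss, 0, tolerance = 1e-12)
})

test_that("RSS approaches n * sigma^2 under additive Gaussian noise", {
  set.seed(121)
  Q <- seq(0.1, 3, length.out = 400)
  base <- 10 * cylinder_form_factor(Q)
  sigma <- 0.05
  noisy <- scattering_curve(Q, base + rnorm(length(Q), 0, sigma))
  m <- match_and_rss(scattering_curve(Q, base), noisy, qrange = c(0.1, 3),
                     weighting = "linear")
  expect_equal(m$rss / m$n, sigma^2, tolerance = 0.25)
})

test_that("RSS is invariant under rescaling of the experimental curve", {
  set.seed(122)
  Q <- seq(0.1, 3, length.out = 100)
  Isim <- cylinder_form_factor(Q)
  sim <- scattering_curve(Q, Isim)
  noisy <- Isim * (1 + rnorm(length(Q), 0, 0.05))
  m1 <- match_and_rss(sim, scattering_curve(Q, noisy), weighting = "log")
  m2 <- match_and_rss(sim, scattering_curve(Q, 1e3 * noisy), weighting = "log")
  expect_equal(m1$rss, m2$rss, tolerance = 1e-9)
  expect_equal(m2$scale / m1$scale, 1e3, tolerance = 1e-6)
})

test_that("reference generator writes a parseable synthetic curve", {
  f <- withr::local_tempfile(fileext = ".dat")
  sch <- mc_schedule(n_equil = 1500, n_prod = 1500, sample_every = 300)
  ref <- make_reference_curve(K = 1, Tstar = 0.14, n = 32, noise = 0.02,
                              schedule = sch, density = 8, n_snapshots = 3,
                              seed = 7, path = f)
  back <- read_saxs_dat(f)
  expect_equal(back$I, ref$I, tolerance = 1e-5)
  expect_true(all(back$sigma > 0))
  md <- attr(ref, "metadata")
  expect_identical(md$source, "synthetic_reference")
})
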