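# Hard-cylinder geometry: shapes, particles, interaction sites, overlap and
# square-well pair energy.

#' Cylinder shape for one G-quadruplex unit
#'
#' A G4 unit is represented as a hard cylinder.  The reference dimensions
#' `D0` (diameter) and `L0` (length) describe the monomeric unit; the
#' dimensionless shape factor `K` deforms the cylinder at a constant
#' diameter-length product: `D = D0 * K`, `L = L0 / K`.  Larger `K` gives a
#' squatter (wider, shorter) cylinder.
#'
#' @param K Dimensionless shape factor (typically explored in 0.8--1.8).
#' @param D0 Reference diameter in nm.
#' @param L0 Reference length in nm.
#'
#' @return An object of class `cylinder_shape` with fields `D0`, `L0`, `K`,
#'   `D` and `L` (all lengths in nm).
#' @examples
#' shp <- cylinder_shape(K = 1.05)
#' shp$D * shp$L == shp$D0 * shp$L0
#' @export
cylinder_shape <- function(K = 1, D0 = 2.12, L0 = 3.10) {
  stopifnot(is.numeric(K), length(K) == 1, K > 0, D0 > 0, L0 > 0)
  structure(
    list(D0 = D0, L0 = L0, K = K, D = D0 * K, L = L0 / K),
    class = "cylinder_shape"
  )
}

#' @export
print.cylinder_shape <- function(x, ...) {
  cat(sprintf("<cylinder_shape> K = %.3g: D = %.4g nm, L = %.4g nm (D0 = %.4g, L0 = %.4g)\n",
              x$K, x$D, x$L, x$D0, x$L0))
  invisible(x)
}

#' Square-well interaction parameters
#'
#' Attractive stacking sites interact through a square well: energy `-u0` if
#' the site-site distance is strictly below the range `delta`, zero otherwise
#' (a site pair exactly at the range boundary counts as non-bonded).  All energies in this
#' package are expressed in units of `u0`, and temperature enters only through
#' the reduced temperature `Tstar = kB*T / u0`.
#'
#' In trimer mode the stacking range narrows to `0.25 * D0` and adjacent
#' cylinders are additionally tethered by covalent rim sites whose distance
#' may not exceed `delta_cov = 0.5 * D0`.
#'
#' @param Tstar Reduced temperature (dimensionless, > 0).
#' @param mode `"monomer"` (self-assembly) or `"trimer"` (covalently linked
#'   triplets).
#' @param delta Square-well range in nm; defaults to 0.5 nm in monomer mode
#'   and `0.25 * D0` in trimer mode.
#' @param D0 Reference diameter used for the trimer-mode defaults, nm.
#'
#' @return An object of class `interaction_params`.
#' @export
interaction_params <- function(Tstar, mode = c("monomer", "trimer"),
                               delta = NULL, D0 = 2.12) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(Tstar), length(Tstar) == 1, Tstar > 0)
  if (is.null(delta)) delta <- if (mode == "monomer") 0.5 else 0.25 * D0
  stopifnot(delta > 0)
  structure(
    list(delta = delta, Tstar = Tstar, mode = mode,
         delta_cov = if (mode == "trimer") 0.5 * D0 else NA_real_),
    class = "interaction_params"
  )
}

# validate/normalize an axis vector; reject clearly non-unit input
check_axis <- function(axis) {
  stopifnot(is.numeric(axis), length(axis) == 3, all(is.finite(axis)))
  n <- sqrt(sum(axis^2))
  if (abs(n - 1) > 1e-6) {
    stop("`axis` must be a unit vector (|axis| = ", format(n), ")", call. = FALSE)
  }
  axis / n
}

#' A single hard-cylinder particle
#'
#' @param center Numeric 3-vector, nm.
#' @param axis Unit 3-vector along the cylinder symmetry axis.
#' @param shape A [cylinder_shape()].
#' @param ex Optional unit 3-vector perpendicular to `axis`, fixing the body
#'   frame azimuth (required for covalent rim sites in trimer mode).
#'
#' @return An object of class `cylinder_particle`.
#' @export
cylinder_particle <- function(center = c(0, 0, 0), axis = c(0, 0, 1),
                              shape = cylinder_shape(), ex = NULL) {
  stopifnot(is.numeric(center), length(center) == 3, inherits(shape, "cylinder_shape"))
  axis <- check_axis(axis)
  if (is.null(ex)) {
    ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    ex <- ref - sum(ref * axis) * axis
    ex <- ex / sqrt(sum(ex^2))
  } else {
    ex <- check_axis(ex)
    ex <- ex - sum(ex * axis) * axis
    ex <- ex / sqrt(sum(ex^2))
  }
  structure(list(center = as.numeric(center), axis = axis, ex = ex, shape = shape),
            class = "cylinder_particle")
}

#' Stacking-site positions of a cylinder particle
#'
#' The two attractive stacking sites sit on the symmetry axis at a signed
#' distance `L/2 + 0.15 * D/2` from the center of mass, just outside each
#' basal face.
#'
#' @param p A [cylinder_particle()].
#' @return A 2 x 3 matrix; row `"plus"` is the site on the `+axis` face, row
#'   `"minus"` on the `-axis` face.
#' @examples
#' p <- cylinder_particle()
#' stacking_site_positions(p)  # z = +/- (3.10/2 + 0.15 * 2.12/2) = +/- 1.709
#' @export
stacking_site_positions <- function(p) {
  stopifnot(inherits(p, "cylinder_particle"))
  off <- site_offset(p$shape)
  out <- rbind(p$center + off * p$axis, p$center - off * p$axis)
  dimnames(out) <- list(c("plus", "minus"), c("x", "y", "z"))
  out
}

site_offset <- function(shape) shape$L / 2 + 0.15 * shape$D / 2

#' Covalent rim-site positions (trimer mode)
#'
#' Covalent tether sites sit on the rim circle of the basal faces: radial
#' distance `D/2` from the axis at axial coordinate `+/- L/2`, in the
#' direction of the particle's body-frame vector `ex`.
#'
#' @param p A [cylinder_particle()].
#' @param faces Which faces to return: `+1`, `-1` or both.
#' @return A matrix with one row per requested face.
#' @export
covalent_site_positions <- function(p, faces = c(1, -1)) {
  stopifnot(inherits(p, "cylinder_particle"), all(faces %in% c(1, -1)))
  out <- t(vapply(faces, function(f) {
    p$center + f * (p$shape$L / 2) * p$axis + (p$shape$D / 2) * p$ex
  }, numeric(3)))
  dimnames(out) <- list(ifelse(faces > 0, "plus", "minus"), c("x", "y", "z"))
  out
}

#' Exact overlap test for two hard cylinders
#'
#' Tests whether two closed finite cylinders (flat caps) intersect.  The test
#' is exact for the convex cylinder bodies: fast segment-segment prefilters
#' (circumscribed-sphere and spherocylinder rejection, proven-contact
#' acceptance) resolve most pairs, and the remaining cap-proximal cases are
#' decided with a GJK boolean intersection on the two convex bodies.
#' Attractive sites carry no excluded volume; the hard core is the cylinder
#' alone.
#'
#' @param a,b [cylinder_particle()] objects.
#' @return `TRUE` iff the cylinders overlap.  Symmetric in its arguments.
#' @examples
#' shp <- cylinder_shape()
#' a <- cylinder_particle(c(0, 0, 0), c(0, 0, 1), shp)
#' b <- cylinder_particle(c(0, 0, 3.0), c(0, 0, 1), shp)
#' cylinders_overlap(a, b)  # coaxial, |dz| < L: TRUE
#' @export
cylinders_overlap <- function(a, b) {
  stopifnot(inherits(a, "cylinder_particle"), inherits(b, "cylinder_particle"))
  as.logical(cylinders_overlap_cpp(
    matrix(a$center, 1), matrix(a$axis, 1),
    matrix(b$center, 1), matrix(b$axis, 1),
    a$shape$D, a$shape$L, b$shape$D, b$shape$L
  ))
}

#' Square-well pair energy of two cylinder particles
#'
#' Sums `-u0` over all stacking-site pairs (one site from each particle)
#' whose separation is strictly below the well range `delta`.  Hard-core
#' overlap is handled separately (as rejection / infinite energy) and is not
#' checked here.
#'
#' @param a,b [cylinder_particle()] objects (assumed non-overlapping).
#' @param params An [interaction_params()].
#' @param u0 Binding energy scale; the default 1 returns energy in units of
#'   `u0`.
#' @return Pair energy (0 or a negative multiple of `u0`).
#' @export
sw_pair_energy <- function(a, b, params, u0 = 1) {
  stopifnot(inherits(params, "interaction_params"))
  sa <- stacking_site_positions(a)
  sb <- stacking_site_positions(b)
  d2 <- outer(seq_len(2), seq_len(2), Vectorize(function(i, j) sum((sa[i, ] - sb[j, ])^2)))
  -u0 * sum(d2 < params$delta^2)
}
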