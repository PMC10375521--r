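---
title: "Coarse-grained modelling of G-quadruplex stacking: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained modelling of G-quadruplex stacking: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

G-quadruplexes (G4s) formed by the human telomeric sequence stack end to end
through their external G-tetrad faces, producing polydisperse multimers whose
signature is an excess of small-angle X-ray scattering (SAXS) intensity below
Q ≈ 1 nm⁻¹. `g4stack` implements an *extremely coarse-grained* description of
this process in which all chemistry is collapsed into four numbers:

* each G4 unit is a **hard cylinder** of diameter $D$ and length $L$.  The
  reference dimensions $D_0 = 2.12$ nm, $L_0 = 3.10$ nm describe the
  monomeric telomeric unit (hydration shell included — there is no explicit
  solvent layer anywhere in the model).  A dimensionless shape factor $K$
  deforms the cylinder at constant $D\,L$ product: $D = D_0 K$, $L = L_0/K$;
* each basal face carries an attractive **stacking site** on the symmetry
  axis at $\pm(L/2 + 0.15\,D/2)$ from the center.  Sites on distinct
  particles interact through a **square well**: energy $-u_0$ when their
  separation is strictly below $\delta$ ($\delta = 0.5$ nm for
  self-assembling monomers), zero otherwise.  A pair exactly at the range
  boundary is non-bonded — the measure-zero convention matching the strict
  inequality of the potential;
* temperature enters only through the **reduced temperature**
  $T^* = k_B T/u_0$: lower $T^*$ means stronger stacking relative to thermal
  energy.  All energies in the package are reported in units of $u_0$.

Because one bond joins two chains, the mean number of stacked units per
aggregate follows from the mean potential energy per particle $\epsilon$ as

$$M = \left(1 - |\epsilon|/u_0\right)^{-1},$$

with $b = |\epsilon|/u_0$ the bonds per particle (all-dimer check:
$b = 1/2 \Rightarrow M = 2$).  We keep the magnitude convention explicit
because with $\epsilon$ negative a literal reading of the formula gives
values below one; the bonds-per-particle bookkeeping reproduces every
reference value.  At equilibrium the chain lengths follow the step-growth
(Flory, exponential) distribution

$$\nu(l) = \rho\, M^{-(l+1)} (M-1)^{l-1},
  \qquad \sum_{l\ge1} l\,\nu(l) = \rho,$$

whose dispersity is $\mathcal{D} = 2 - 1/M$.  These identities are enforced
by tests to machine precision.

### Trimer mode

Long telomeric sequences carrying three G4-forming units (Tel72) are
modelled as three hard cylinders tethered by **covalent rim sites** on the
edges of facing bases: the tether distance may not exceed
$0.5\,D_0 = 1.06$ nm, implemented as pure rejection (no restoring force).
Stacking sites persist on the internal faces only — terminal outward faces
carry none, so distinct trimers do not stack — and the stacking range
narrows to $0.25\,D_0 = 0.53$ nm.  A rim site breaks the cylinder's
azimuthal symmetry, so trimer-mode particles carry a full body frame; both
rim sites of the middle cylinder sit at the same body azimuth (the model
figures do not resolve this choice; placing them on opposite azimuths would
only re-label the body frame of a symmetric particle, and the observables
we report are insensitive to it at the resolution of the study).

## Monte Carlo sampling

Sampling is canonical ($NVT^*$) Metropolis with single-particle moves (50%
translations uniform in a cube, 50% rotations about a random axis), periodic
boundary conditions, and number density fixed by the molar concentration,
$\rho = N_\mathrm{av} C$.  Initial configurations are orthorhombic lattices
(stacked coaxial triplets in trimer mode); construction fails explicitly if
the requested density does not admit non-overlapping lattice placement.
Implementation choices that matter:

* **Overlap test.**  The flat-capped cylinder is convex, so exactness is
  cheap: a circumscribed-sphere reject, a spherocylinder reject
  (segment–segment distance $\ge D$), a proven-overlap accept when the axes'
  closest points are interior to both segments and closer than $D$, and a
  GJK boolean intersection for the remaining cap-proximal cases.  A
  non-converged GJK (grazing contact) is counted as overlap — conservative
  for hard-core sampling and of vanishing measure.  The predicate is
  validated against a point-membership sampling oracle: a sampled point
  common to both bodies is an exact certificate of intersection, so any
  certificate against a negative predicate is a hard failure.
* **Cell lists** with edge at least the larger of the hard-core and
  site-reach diameters give O(1) moves; boxes smaller than three cells fall
  back to all-pairs evaluation, with identical results.
* **Move amplitudes** are auto-tuned during equilibration only (toward
  acceptance between 0.3 and 0.5, capped at box/4 and π) and frozen for
  production, so detailed balance holds where samples are taken.  In the
  dilute regimes studied here acceptance saturates near the caps, which
  maximizes diffusion between distant partners.
* A **single RNG stream** drives each run (R's generator, so `set.seed`
  and the stored `rng_seed` make runs bit-reproducible).
* The cached total energy is validated against full recomputation at every
  snapshot (tolerance $10^{-9} u_0$).

### Equilibration

"One MC step" is read as one attempted single-particle move; a sweep is $N$
attempts.  The full-scale reference runs use millions of steps; the package
instead judges equilibration by **stationarity of the energy trace** — a
Mann–Kendall trend test on a thinned window (thinning keeps sweep-to-sweep
autocorrelation from inflating the trend signal).  This is the criterion
the method itself states (the energy must attain a stationary value), not a
fixed step count.  The slow mode is bond turnover: a bond at $T^*$ breaks
with probability $\sim e^{-1/T^*}$ per proposal, so at $T^* = 0.085$ bond
lifetimes reach $\sim 10^5$ sweeps and runs at the multimeric state points
use several times that for equilibration.  `fit_grid` flags grid points
whose trace still trends and excludes them from the argmin.

## Scattering

**Intensity.**  Following the scattering-point method, every cylinder is
replaced by a Poisson number of uniform random points (default density
20 nm⁻³, ≈218 points per reference cylinder; fresh fills per snapshot
decorrelate the fill noise) and the orientationally averaged intensity is
the Debye sum $I(Q) = \sum_{j \ne k} \sin(Qr_{jk})/(Qr_{jk})$ over
*distinct* point pairs.  The self term is deliberately excluded: it is the
flat shot-noise floor of the discretization, absent from a continuous
scattering density, and retaining it biases exactly the high-$Q$ region
where the form factor is small.  With the $N\bar p(\bar p - 1)$
normalization an isolated cylinder returns an unbiased estimate of its
analytic form factor

$$P(Q) = \int_0^{\pi/2} \left[\frac{2 J_1(QR\sin\alpha)}{QR\sin\alpha}\,
  \mathrm{sinc}\!\left(\tfrac{QL}{2}\cos\alpha\right)\right]^2
  \sin\alpha\, d\alpha,$$

which serves as the package's independent oracle (quadrature by `integrate`
at `rel.tol = 1e-10`, cross-checked against a fine midpoint rule).

By default the coherent sum runs over point pairs **within the same
multimer** (bond-graph component, or covalent trimer) — the dilute-solution
approximation.  Inter-multimer interference in a periodic box of a few
hundred particles contaminates low $Q$ with finite-size oscillations of
order $\cos(Q\,\mathrm{box}/2)/Q^2$, which the experiment (at macroscopic
$N$) does not have; dropping the cross terms removes the artifact and makes
an ideal monomeric system return exactly $N P(Q)$, the observed monomer
plateau.  The inter-particle correlations are reported separately through
the center-of-mass structure factor, which at the studied dilutions is
essentially 1 over the fitted window; a `cross = "all"` option keeps every
pair for completeness.

**Structure factor.**  $S(Q)$ from particle centers uses the minimum-image
pair histogram to half the box edge with the analytic ideal-gas background
subtracted (the shell volume $4\pi r^2\,dr/V$ is exact for $r \le
\mathrm{box}/2$ under the minimum-image metric), so an uncorrelated system
gives $S(Q) = 1$ up to sampling noise.  The stacking signature is the first
peak at $Q \approx 2$ nm⁻¹, i.e. a nearest-neighbor distance of ≈3.1 nm.

## Thermodynamics

From a fitted $(T^*, M)$ state point at $T = 293$ K
(with $k_B = 1.987\times10^{-3}$ kcal mol⁻¹ K⁻¹):

* stacking free energy $G_\mathrm{ST}^0 = -k_B T \ln[M(M-1)]$ — zero at the
  golden ratio, positive for weakly multimerized systems;
* enthalpy $H_\mathrm{ST}^0 = -u_0 = -k_B T/T^*$ (the full well depth per
  bond, as the square well has no internal temperature dependence);
* entropy $S_\mathrm{ST}^0 = 1000\,(H - G)/T$ in cal mol⁻¹ K⁻¹.

This decomposition reproduces all four tabulated reference values to their
printed precision.  Two ambiguities are worth recording.  First, the
reference tabulation describes $G_\mathrm{ST}^0$ as computed at a standard
concentration of 1 M, yet the formula as printed reproduces every tabulated
number with no concentration term; the package computes the formula as
printed and exposes an optional standard-state correction hook
(`conc` argument, default off).  Second, the enthalpy/entropy route is not
stated explicitly in the source material; $H = -u_0$ with $S = (H-G)/T$ is
the unique simple decomposition consistent with all printed values and is
adopted with that caveat.

## Fitting (K, T*)

`fit_grid` is a plain grid search, as in the original study — no continuous
optimizer, no posterior.  At each $(K, T^*)$ a simulation is run (or reused
from a cache keyed by all settings), its Debye intensity is interpolated
onto the experimental grid, the arbitrary simulation scale is profiled
analytically, and the residual sum of squares is recorded.  Unstated
protocol details are declared as defaults rather than inferred: RSS on
$\log_{10} I$ with unit weights over $Q \in [0.05, 3]$ nm⁻¹ (the window
where the coarse-grained model is informative; the high-$Q$ region reflects
sub-cylinder structure the model cannot capture), with linear and
σ-weighted options, and an optional flat background for the linear routes.
Ties in the argmin break toward the lowest $T^*$ and are listed.  Because
the experimental curves of the original study are not deposited, the
package generates **synthetic references** with its own pipeline
(`make_reference_curve`, multiplicative Gaussian noise, default 2%) and
demonstrates parameter recovery round-trips at grid resolution; reference
and grid simulations share the schedule so that scaled-down equilibration
bias cancels in the comparison.  One identifiability caveat: the $T^*$
signal in $I(Q)$ is the low-$Q$ multimerization excess, of order $M - 1$,
so in the monomeric limit ($M \to 1$, $T^* \gtrsim 0.14$ at these
concentrations) neighbouring $T^*$ grid points produce curves degenerate to
within any realistic noise level — the fit then determines $K$ sharply but
only a lower bound on $T^*$.  Round-trip demonstrations therefore use a
visibly multimerizing reference state.

## What the synthetic data do and do not show

The synthetic generator *is* the model: passing round-trips demonstrates
that the pipeline is self-consistent and that the scaled-down state points
reproduce the published observables (average chain length, structure-factor
peak, trimer bond-class fractions, angle modes).  It does not demonstrate
that a hard cylinder with two square-well patches is the right description
of a real G4 — that case is made by the agreement with experimental SAXS in
the original study.  Real curves additionally contain instrument smearing,
buffer-subtraction residuals and concentration-dependent inter-particle
interference, none of which the generator emulates.

## Problem sizes and numerical choices

Simulated checks in the test-suite and acceptance script use $N = 200$–$650$
particles and $10^4$–$5\times10^5$ sweeps per state point — a deliberate
scale-down from the full-size study ($N = 6292$ monomers, 2000 trimers).
$M$ is intensive, and the test suite verifies that doubling the system
leaves it unchanged within sampling error, so the scaled systems measure
the same thermodynamics with wider error bars; the published $M$ values
carry ≈10% uncertainty and all comparisons use that tolerance.  Other fixed
choices: overlap decisions carry a $10^{-9}$ nm slack on separating
distances (the measured $M$ is insensitive to this at the $10^{-3}$ level);
attractive sites carry no excluded volume (the hard core is the cylinder
alone, matching the potential's definition); the trimer mass concentration
of 10 mg/mL converts to number density with a molar mass of 22,600 g/mol
(configurable) for the twelve-repeat telomeric sequence; histogram bin
widths are 0.02 nm for $S(Q)$ and 0.002 nm for binned Debye sums, well
below the shortest length scales probed.

## Known limitations

* Sampling, not kinetics: single-particle Metropolis moves give equilibrium
  averages; no dynamical quantity is meaningful.
* No electrostatics, explicit ions or soft repulsion — ionic-strength
  effects enter only implicitly through the fitted $(K, T^*)$.
* The intensity normalization is arbitrary (scale is profiled in fitting);
  absolute calibration to cm⁻¹ is out of scope.
* At strongly stacking state points ($T^* \lesssim 0.08$) bond turnover
  becomes so slow that scaled-down runs need $\gtrsim 10^6$ sweeps;
  `fit_grid` will flag such points rather than silently report them.
* Branch nodes (three chains meeting at one site pair) are geometrically
  suppressed but not impossible; they are counted and reported, never
  silently dropped.
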