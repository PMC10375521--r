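Package: g4stack
Title: Coarse-Grained Monte Carlo Modelling of G-Quadruplex Multimer
    Stacking and Small-Angle Scattering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extremely coarse-grained (patchy hard-cylinder) Metropolis Monte
    Carlo simulation of G-quadruplex (G4) multimerization driven by coaxial
    stacking.  Each G4 unit is a hard cylinder decorated with short-range
    square-well sites on its bases; canonical-ensemble sampling yields chain
    statistics (average multimer length, dispersity, inter-unit angles,
    gyration radii, structure factor), SAXS-comparable scattering intensities
    by the scattering-point Debye method, stacking thermodynamics (standard
    free energy, enthalpy and entropy of stacking), and a grid fit of the
    cylinder shape factor K and reduced temperature T* against experimental
    small-angle scattering curves.  Supports both self-assembling monomers
    and covalently tethered trimers (beads-on-a-string analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
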