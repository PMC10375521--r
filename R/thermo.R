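# Stacking thermodynamics: standard free energy, enthalpy and entropy from
# the fitted (T*, M) state point.

#' Coaxial stacking free energy from the average chain length
#'
#' `G_ST = -kB * T * ln[M (M - 1)]` in kcal/mol, with
#' `kB = 1.987e-3 kcal mol^-1 K^-1`.  Positive for weakly multimerized
#' systems (`M (M - 1) < 1`, i.e. `M` below the golden ratio) and zero
#' exactly at `M = (1 + sqrt(5)) / 2`.
#'
#' The formula as printed carries no explicit concentration term; an optional
#' standard-state correction hook is exposed through `conc` (mol/L), which
#' when supplied adds `-kB * T * ln(conc / conc_ref)`.  It is off by default:
#' the reference tabulated values are reproduced without it.
#'
#' @param M Average chain length, must exceed 1.
#' @param T Temperature in K (standard value 293 K).
#' @param conc Optional molar concentration for the standard-state hook.
#' @param conc_ref Reference concentration for the hook, mol/L.
#' @return Free energy in kcal/mol.
#' @examples
#' stacking_free_energy(1.66)  # -0.05 kcal/mol
#' stacking_free_energy(1.13)  # +1.12 kcal/mol
#' @export
stacking_free_energy <- function(M, T = 293, conc = NULL, conc_ref = 1) {
  if (any(M <= 1)) {
    stop("`M` must exceed 1: ln[M(M-1)] is undefined for M <= 1 ",
         "(no multimerization signal)", call. = FALSE)
  }
  G <- -KB_KCAL * T * log(M * (M - 1))
  if (!is.null(conc)) G <- G - KB_KCAL * T * log(conc / conc_ref)
  G
}

#' Standard stacking enthalpy and entropy
#'
#' The enthalpic contribution is the full well depth per stacking bond,
#' `H_ST0 = -u0 = -kB * T / T*` (kcal/mol); the entropic contribution
#' follows from the free energy, `S_ST0 = 1000 * (H - G) / T`
#' (cal mol^-1 K^-1).
#'
#' @param Tstar Reduced temperature of the fitted state point.
#' @param M Average chain length (> 1), used for `G`.
#' @param T Temperature in K.
#' @return A list with `H` (kcal/mol) and `S` (cal mol^-1 K^-1).
#' @examples
#' enthalpy_entropy(0.09, 1.66)  # H = -6.47 kcal/mol, S = -21.9 cal/mol/K
#' @export
enthalpy_entropy <- function(Tstar, M, T = 293) {
  stopifnot(Tstar > 0)
  H <- -KB_KCAL * T / Tstar
  G <- stacking_free_energy(M, T)
  list(H = H, S = 1000 * (H - G) / T)
}

#' Full stacking thermodynamics summary for a state point
#'
#' @param M Average chain length (> 1).
#' @param Tstar Reduced temperature.
#' @param T Temperature in K.
#' @return A one-row tibble: `Tstar`, `M`, `dispersity`, `G_ST0`
#'   (kcal/mol), `H_ST0` (kcal/mol), `S_ST0` (cal mol^-1 K^-1), `T`.
#' @export
stacking_thermo <- function(M, Tstar, T = 293) {
  hs <- enthalpy_entropy(Tstar, M, T)
  tibble::tibble(
    Tstar = Tstar, M = M, dispersity = dispersity(M),
    G_ST0 = stacking_free_energy(M, T), H_ST0 = hs$H, S_ST0 = hs$S, T = T
  )
}
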