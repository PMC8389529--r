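## Physical constants and unit conventions.
##
## Internal units throughout: length nm, energy kcal/mol, time ps,
## temperature K, mass amu. File readers convert from Angstrom (PDB, XYZ,
## volumes) on input; volumes are reported in A^3 as is customary for
## standard-state corrections.

#' Boltzmann constant in kcal/mol/K
#'
#' @keywords internal
#' @noRd
.kB <- 0.0019872

## kcal/mol -> kJ/mol, needed to make (kcal/mol, nm, amu, ps) dynamics
## consistent: F[kJ/mol/nm] / m[amu] = a[nm/ps^2].
.KCAL2KJ <- 4.184

#' Thermal energy kT
#'
#' Thermal energy at a given temperature, in kcal/mol. At 300 K this is
#' 0.59616 kcal/mol.
#'
#' @param temperature Temperature in kelvin.
#' @return Energy in kcal/mol.
#' @examples
#' kT(300)
#' @export
kT <- function(temperature = 300) {
  stopifnot(is.numeric(temperature), temperature >= 0)
  .kB * temperature
}

#' Standard-state volume per molecule at 1 M
#'
#' Volume available to one molecule at a 1 mol/L concentration,
#' \eqn{V^\circ = 10^{27} / N_A} cubic Angstrom. Rounds to the customary
#' 1661 A^3 used in standard binding free energy corrections.
#'
#' @param exact If `TRUE` (default) return the unrounded value computed
#'   from Avogadro's number; if `FALSE` return the conventional rounded
#'   1661 A^3.
#' @return Volume in A^3.
#' @examples
#' standard_volume()        # 1660.539...
#' standard_volume(FALSE)   # 1661
#' @export
standard_volume <- function(exact = TRUE) {
  v <- 1e27 / 6.02214076e23
  if (exact) v else round(v)
}
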