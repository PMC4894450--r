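#' Unit conversions and cell-wall energy bookkeeping
#'
#' The package works in micrometres, minutes and nanonewtons throughout, so
#' pressures are stored as nN/um^2 and energies as nN um.  These helpers
#' perform the few conversions that cross that system's boundary.
#'
#' @param mpa pressure in MPa.
#' @return `mpa_to_nn_um2()`: the same pressure in nN/um^2 (1 MPa = 1000 nN/um^2).
#' @export
mpa_to_nn_um2 <- function(mpa) {
  stopifnot(is.numeric(mpa))
  1000 * mpa
}

#' Thermal energy in nN um
#'
#' @param temp_c temperature in degrees Celsius.
#' @return k_B * T expressed in nN um (1 J = 1e15 nN um).
#' @export
thermal_energy <- function(temp_c = 31) {
  kb_j <- 1.380649e-23
  kb_j * (273.15 + temp_c) * 1e15
}

#' Number of peptidoglycan subunits tiling a cell-wall area
#'
#' A subunit is taken as one glycan strand segment cross-linked by a peptide
#' chain, so it occupies roughly `strand_nm * peptide_nm` of wall area.
#'
#' @param area_um2 cell-wall surface area in um^2.
#' @param strand_nm glycan strand length per subunit, nm.
#' @param peptide_nm stretched peptide cross-link length, nm.
#' @return approximate subunit count.
#' @export
peptidoglycan_subunits <- function(area_um2, strand_nm = 5, peptide_nm = 4) {
  stopifnot(area_um2 > 0, strand_nm > 0, peptide_nm > 0)
  area_um2 / (strand_nm * peptide_nm * 1e-6)
}

#' Mechanical energy consumed per peptidoglycan subunit
#'
#' @param total_energy_nn_um net mechanical energy used for wall growth, nN um.
#' @param n_subunits number of subunits sharing it.
#' @return energy per subunit in nN um.
#' @export
energy_per_subunit <- function(total_energy_nn_um, n_subunits) {
  stopifnot(n_subunits > 0)
  total_energy_nn_um / n_subunits
}
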