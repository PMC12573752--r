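#' @title Physical constants and element data
#' @description Internal unit conventions: Hartree atomic units everywhere
#'   inside the package (lengths in bohr, energies in Hartree, charges in e,
#'   dipoles in e*bohr).  Angstrom and kcal/mol appear only at I/O boundaries.
#' @name units
NULL

#' Bohr radii per Angstrom
#' @export
BOHR_PER_ANGSTROM <- 1.8897259886

#' kcal/mol per Hartree
#' @export
KCAL_PER_HARTREE <- 627.509

#' Debye per e*bohr
#' @export
DEBYE_PER_EBOHR <- 2.541746473

#' Convert Angstrom to bohr
#' @param x length(s) in Angstrom
#' @return length(s) in bohr
#' @export
ang_to_bohr <- function(x) x * BOHR_PER_ANGSTROM

#' Convert bohr to Angstrom
#' @param x length(s) in bohr
#' @return length(s) in Angstrom
#' @export
bohr_to_ang <- function(x) x / BOHR_PER_ANGSTROM

#' Convert Hartree to kcal/mol
#' @param x energy in Hartree
#' @return energy in kcal/mol
#' @export
ha_to_kcal <- function(x) x * KCAL_PER_HARTREE

#' Convert kcal/mol to Hartree
#' @param x energy in kcal/mol
#' @return energy in Hartree
#' @export
kcal_to_ha <- function(x) x / KCAL_PER_HARTREE

# Per-element defaults: valence electron count N, Gaussian widths (bohr) for
# the permanent-charge and dipole densities, pseudopotential core smearing
# sigma_core (bohr), isotropic polarizability alpha (bohr^3).  Widths are
# calibration parameters (see fit_widths); the values here are the package's
# declared starting points for water.
.element_table <- list(
  H  = list(Z = 1,  N = 1, sigma_q = 1.0, sigma_mu = 1.1, sigma_core = 0.60,
            alpha = 1.98),
  O  = list(Z = 8,  N = 6, sigma_q = 1.2, sigma_mu = 1.3, sigma_core = 0.70,
            alpha = 8.84),
  Cl = list(Z = 17, N = 7, sigma_q = 1.6, sigma_mu = 1.7, sigma_core = 0.90,
            alpha = 15.0)
)

#' Look up per-element defaults
#'
#' @param element element symbol (e.g. "O", "H")
#' @return list with valence count `N`, Gaussian widths `sigma_q`, `sigma_mu`,
#'   core smearing `sigma_core` (all bohr) and polarizability `alpha` (bohr^3)
#' @export
element_defaults <- function(element) {
  e <- .element_table[[element]]
  if (is.null(e)) stop("unknown element: ", element)
  e
}
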