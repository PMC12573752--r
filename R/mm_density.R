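#' @title Backward mapping: force-field multipoles to smooth electron density
#' @description An MM site with permanent charge q and valence count N is
#'   assigned the valence electron density (N - q) g_sigma(r - R) with
#'   g_sigma a normalized Gaussian; an induced point dipole mu is mapped to
#'   -mu . grad g_sigma(r - R).  The atomic core (charge +N) is represented
#'   by an analytic local pseudopotential with a -N/r tail.  All fields are
#'   assembled in reciprocal space, so periodic images are summed exactly.
#' @name mm_density
NULL

#' Create an MM site
#'
#' @param position cartesian position, bohr
#' @param element element symbol (defaults for unspecified parameters)
#' @param q permanent (net) charge, e
#' @param N valence electron count of the isolated atom, e
#' @param sigma_q width of the permanent-charge Gaussian, bohr
#' @param sigma_mu width of the dipole Gaussian, bohr
#' @param sigma_core core smearing of the local pseudopotential, bohr
#'   (default: half of `sigma_q`)
#' @param alpha isotropic dipole polarizability, bohr^3
#' @param k_SE self-energy correction constant, Ha/(e bohr)^2
#' @return object of class `dfq_mm_site`
#' @export
mm_site <- function(position, element, q, N = NULL, sigma_q = NULL,
                    sigma_mu = NULL, sigma_core = NULL, alpha = NULL,
                    k_SE = 0) {
  ed <- element_defaults(element)
  if (is.null(N)) N <- ed$N
  if (is.null(sigma_q)) sigma_q <- ed$sigma_q
  if (is.null(sigma_mu)) sigma_mu <- ed$sigma_mu
  if (is.null(sigma_core)) sigma_core <- sigma_q / 2
  if (is.null(alpha)) alpha <- ed$alpha
  stopifnot(length(position) == 3, all(is.finite(position)),
            sigma_q > 0, sigma_mu > 0, sigma_core > 0, alpha >= 0, N >= 0)
  structure(list(position = as.numeric(position), element = element,
                 q = q, N = N, sigma_q = sigma_q, sigma_mu = sigma_mu,
                 sigma_core = sigma_core, alpha = alpha, k_SE = k_SE),
            class = "dfq_mm_site")
}

#' Create an induced dipole attached to an MM site
#'
#' @param site_index index into the site list
#' @param mu dipole vector, e bohr
#' @param mu_ref isolated-MM reference dipole mu' (for the self-energy
#'   correction k_SE |mu - mu'|^2)
#' @return object of class `dfq_induced_dipole`
#' @export
induced_dipole <- function(site_index, mu = c(0, 0, 0), mu_ref = c(0, 0, 0)) {
  stopifnot(all(is.finite(mu)), all(is.finite(mu_ref)), length(mu) == 3)
  structure(list(site_index = as.integer(site_index),
                 mu = as.numeric(mu), mu_ref = as.numeric(mu_ref)),
            class = "dfq_induced_dipole")
}

.check_resolvable <- function(sigma, grid, what) {
  if (sigma < 1.5 * max(grid$spacing))
    stop(what, " width ", format(sigma),
         " bohr is under-resolved on this grid (max spacing ",
         format(max(grid$spacing)), " bohr; need sigma >= 1.5 * spacing)")
}

#' Valence electron density of one MM site's permanent charge
#'
#' A periodic-image-summed normalized Gaussian carrying N - q electrons.
#'
#' @param site `dfq_mm_site`
#' @param grid `dfq_grid`
#' @return `dfq_field`
#' @export
charge_density <- function(site, grid) {
  .check_resolvable(site$sigma_q, grid, "permanent-charge Gaussian")
  .field_from_coeff(grid, .gaussian_coeff(grid, site$position, site$sigma_q,
                                          site$N - site$q))
}

#' Electron density carried by one induced point dipole
#'
#' rho_mu(r) = -mu . grad g_sigma(r - R); integrates to zero, first moment
#' equal to the dipole (in the electron-density sign convention, where the
#' physical charge density is minus the electron density).
#'
#' @param d `dfq_induced_dipole`
#' @param site `dfq_mm_site` the dipole sits on
#' @param grid `dfq_grid`
#' @return `dfq_field`
#' @export
dipole_density <- function(d, site, grid) {
  .check_resolvable(site$sigma_mu, grid, "dipole Gaussian")
  if (all(d$mu == 0)) return(scalar_field(grid, 0))
  # FT of -mu . grad g = -i (mu . G) ghat
  ghat <- exp(-0.5 * site$sigma_mu^2 * grid$g2) *
    .phase_factors(grid, site$position) / grid$volume
  cG <- -1i * (d$mu[1] * grid$gx + d$mu[2] * grid$gy + d$mu[3] * grid$gz) * ghat
  .field_from_coeff(grid, cG)
}

#' Assemble the total MM valence electron density
#'
#' Sum of all permanent-charge Gaussians and dipole-gradient densities;
#' integrates to sum(N_i - q_i) regardless of the dipole values.
#'
#' @param sites list of `dfq_mm_site`
#' @param dipoles list of `dfq_induced_dipole` (may be empty)
#' @param grid `dfq_grid`
#' @return `dfq_field`
#' @export
assemble_mm_density <- function(sites, dipoles = list(), grid) {
  cG <- array(0i, dim = grid$shape)
  for (s in sites) {
    .check_resolvable(s$sigma_q, grid, "permanent-charge Gaussian")
    cG <- cG + .gaussian_coeff(grid, s$position, s$sigma_q, s$N - s$q)
  }
  for (d in dipoles) {
    if (d$site_index < 1 || d$site_index > length(sites))
      stop("dipole references site ", d$site_index, " but only ",
           length(sites), " sites exist")
    s <- sites[[d$site_index]]
    .check_resolvable(s$sigma_mu, grid, "dipole Gaussian")
    if (all(d$mu == 0)) next
    ghat <- exp(-0.5 * s$sigma_mu^2 * grid$g2) *
      .phase_factors(grid, s$position) / grid$volume
    cG <- cG - 1i * (d$mu[1] * grid$gx + d$mu[2] * grid$gy +
                       d$mu[3] * grid$gz) * ghat
  }
  .field_from_coeff(grid, cG)
}

# local pseudopotential of a set of cores in reciprocal space:
# v_loc(r) = -N erf(r / (sqrt(2) sigma_core)) / r, i.e. the (attractive)
# Coulomb potential of a Gaussian core of charge N acting on an electron.
.ionic_potential <- function(positions, Ns, sigmas, grid) {
  cG <- array(0i, dim = grid$shape)
  for (i in seq_along(Ns)) {
    cG <- cG + .gaussian_coeff(grid, positions[[i]], sigmas[i], -Ns[i]) *
      grid$coulG
  }
  .field_from_coeff(grid, cG)
}

#' Ionic local potential of the MM cores
#'
#' v_MM(r) = sum_i v_loc(|r - R_i|) with v_loc(r) = -N erf(r/(sqrt(2)
#' sigma_core))/r: attractive for electrons, -N/r at long range, evaluated
#' with the same neutralizing-background (G = 0 removed) convention as
#' `solve_hartree`.
#'
#' @param sites list of `dfq_mm_site`
#' @param grid `dfq_grid`
#' @return `dfq_field` (Ha per electron)
#' @export
mm_ionic_potential <- function(sites, grid) {
  if (length(sites) == 0) return(scalar_field(grid, 0))
  .ionic_potential(lapply(sites, `[[`, "position"),
                   vapply(sites, `[[`, numeric(1), "N"),
                   vapply(sites, `[[`, numeric(1), "sigma_core"),
                   grid)
}

# smeared ionic (core) charge density, +N Gaussians of width sigma_core
.ionic_charge_density <- function(positions, Ns, sigmas, grid) {
  cG <- array(0i, dim = grid$shape)
  for (i in seq_along(Ns)) {
    cG <- cG + .gaussian_coeff(grid, positions[[i]], sigmas[i], Ns[i])
  }
  .field_from_coeff(grid, cG)
}

# Gaussian self-energy q^2 / (2 sqrt(pi) sigma) of each core, used to remove
# self-interaction from grid-computed ion-ion energies
.ionic_self_energy <- function(Ns, sigmas) {
  sum(Ns^2 / (2 * sqrt(pi) * sigmas))
}
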