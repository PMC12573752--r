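#' @title Nonadditive interaction energy and embedding objects
#' @description The subsystem-DFT interaction core: for two fragment
#'   densities rho_A, rho_B with external (ionic) potentials v_A, v_B, the
#'   nonadditive energy is
#'   T_s^nad + E_xc^nad + int rho_A rho_B / |r - r'| + int rho_B v_A
#'   + int rho_A v_B, with F^nad = F[rho_A + rho_B] - F[rho_A] - F[rho_B]
#'   for the kinetic and xc functionals.  Its functional derivative with
#'   respect to one fragment's density is that fragment's embedding
#'   potential.
#' @name nonadditive
NULL

#' Nonadditive energy breakdown of two fragment densities
#'
#' @param rhoA,rhoB `dfq_field` electron densities on the same grid
#' @param vA,vB `dfq_field` ionic potentials of each fragment
#' @param cfg `dfq_kinetic_config` for the nonadditive kinetic functional
#'   (default: the GGA form)
#' @param include_kinetic,include_xc include T_s^nad / E_xc^nad (diagnostic
#'   switches; both TRUE for physical runs)
#' @return object of class `dfq_energy_breakdown` with fields `T_s_nad`,
#'   `E_xc_nad`, `E_coul_cross`, `E_ext_cross_AonB` (rho_B in v_A),
#'   `E_ext_cross_BonA` (rho_A in v_B) and `total_nad` (all Ha)
#' @export
nonadditive_energy <- function(rhoA, rhoB, vA, vB,
                               cfg = kinetic_config("GGA"),
                               include_kinetic = TRUE, include_xc = TRUE) {
  .check_same_grid(rhoA, rhoB); .check_same_grid(rhoA, vA)
  .check_same_grid(rhoA, vB)
  g <- rhoA$grid
  kin <- if (include_kinetic) cfg else NULL
  tot <- .sl_combined(g, rhoA$values + rhoB$values, kin_cfg = kin,
                      with_xc = include_xc, need_potential = FALSE)
  a <- .sl_combined(g, rhoA$values, kin_cfg = kin, with_xc = include_xc,
                    need_potential = FALSE)
  b <- .sl_combined(g, rhoB$values, kin_cfg = kin, with_xc = include_xc,
                    need_potential = FALSE)
  ts_nad <- tot$e_kin - a$e_kin - b$e_kin
  exc_nad <- tot$e_xc - a$e_xc - b$e_xc
  phiB <- .ifftn_re(b$rho_hat * g$coulG)
  e_coul <- sum(rhoA$values * phiB) * g$voxel
  e_BinA <- sum(rhoB$values * vA$values) * g$voxel
  e_AinB <- sum(rhoA$values * vB$values) * g$voxel
  structure(list(T_s_nad = ts_nad, E_xc_nad = exc_nad,
                 E_coul_cross = e_coul,
                 E_ext_cross_AonB = e_BinA, E_ext_cross_BonA = e_AinB,
                 total_nad = ts_nad + exc_nad + e_coul + e_BinA + e_AinB),
            class = "dfq_energy_breakdown")
}

#' Embedding potential acting on a QM density
#'
#' v_emb = v_MM + Hartree(rho_MM) + dT_s^nad/drho_QM + dE_xc^nad/drho_QM,
#' the functional derivative of the nonadditive energy with respect to the
#' QM density.  The semilocal derivatives are evaluated in potential-
#' difference form v_F[rho_QM + rho_MM] - v_F[rho_QM], exact for any
#' semilocal functional.
#'
#' @param rhoQM,rhoMM `dfq_field` densities on the same grid
#' @param vMM `dfq_field` MM ionic potential
#' @param cfg `dfq_kinetic_config` for the nonadditive kinetic functional
#' @param include_kinetic,include_xc diagnostic switches (see
#'   `nonadditive_energy`)
#' @return `dfq_field` (Ha per electron)
#' @export
embedding_potential_qm <- function(rhoQM, rhoMM, vMM,
                                   cfg = kinetic_config("GGA"),
                                   include_kinetic = TRUE,
                                   include_xc = TRUE) {
  .check_same_grid(rhoQM, rhoMM); .check_same_grid(rhoQM, vMM)
  g <- rhoQM$grid
  kin <- if (include_kinetic) cfg else NULL
  tot <- .sl_combined(g, rhoQM$values + rhoMM$values, kin_cfg = kin,
                      with_xc = include_xc)
  qm <- .sl_combined(g, rhoQM$values, kin_cfg = kin, with_xc = include_xc)
  phiMM <- solve_hartree(rhoMM)
  scalar_field(g, vMM$values + phiMM$values + tot$v - qm$v)
}

#' Electric field of the QM charge distribution at MM sites
#'
#' The classical-electrostatics part of the MM embedding response: the
#' field of the total QM charge density (smeared ionic cores minus
#' electrons), i.e. the first two terms of the MM embedding potential with
#' the short-range kinetic/xc terms excluded by design.  In per-electron
#' potential terms the sampled quantity is grad(v_QM + Hartree(rho_QM)),
#' which equals the physical field -grad(phi) of the QM charge density
#' acting on a positive test charge.  The field is evaluated at the grid
#' point nearest each site (ties toward the lower index).
#'
#' @param rhoQM `dfq_field` QM electron density
#' @param vQM `dfq_field` QM ionic potential
#' @param sites list of `dfq_mm_site`
#' @return n x 3 matrix of field vectors (Ha/(e bohr))
#' @export
qm_field_at_mm_sites <- function(rhoQM, vQM, sites) {
  .check_same_grid(rhoQM, vQM)
  g <- rhoQM$grid
  phiH <- solve_hartree(rhoQM)
  w <- vQM$values + phiH$values
  gr <- .grad_arrays(g, w)
  E <- matrix(0, length(sites), 3)
  for (i in seq_along(sites)) {
    idx <- nearest_grid_index(g, sites[[i]]$position)
    E[i, ] <- c(gr[[1]][idx[1], idx[2], idx[3]],
                gr[[2]][idx[1], idx[2], idx[3]],
                gr[[3]][idx[1], idx[2], idx[3]])
  }
  E
}

#' Serialize an energy breakdown to a flat key/value report
#'
#' @param x `dfq_energy_breakdown` or any named list of energies in Ha
#' @param path optional output file; when NULL the lines are returned
#' @return character vector of report lines, invisibly when written
#' @export
energy_report <- function(x, path = NULL) {
  nm <- names(x)
  keep <- vapply(x, function(v) is.numeric(v) && length(v) == 1, logical(1))
  lines <- sprintf("%-22s %20.10f Ha %18.6f kcal/mol",
                   nm[keep], unlist(x[keep]), ha_to_kcal(unlist(x[keep])))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
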