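#' @title Forward mapping: Gaussian-width calibration and partition statistics
#' @description Fits the element-specific Gaussian widths of the MM electron
#'   density (and optionally the dipole self-energy constants) so that
#'   model QM/MM interaction energies reproduce reference energies, and
#'   implements the fragment-partition RMSE statistic with the
#'   error-per-boundary conversion slope * sqrt(pi/2).
#' @name sigma_fitting
NULL

#' Build a width-fitting problem from labeled configurations
#'
#' Precomputes, for each configuration, the frozen isolated-QM density, the
#' induced dipoles under the frozen QM field, and all width-independent
#' energy terms, so that the fit objective only needs to reassemble the MM
#' density and re-evaluate the nonadditive terms for each trial width
#' vector.  The QM density is not re-relaxed during the fit (frozen-density
#' approximation), which keeps the calibration at interaction-energy level
#' while remaining fast enough for bounded optimization.
#'
#' @param configs list of `dfq_geometry` with QM/MM roles and a shared cell
#' @param model `dfq_mm_model` supplying everything except the fitted widths
#' @param cutoff grid energy cutoff, Ha
#' @param kin_add,kin_nad kinetic-functional configurations
#' @param reference_energies optional numeric vector (kcal/mol); when NULL,
#'   fill in later with `$reference`
#' @return object of class `dfq_fit_problem`
#' @export
width_fit_problem <- function(configs, model = mm_model(), cutoff = 20,
                              kin_add = kinetic_config("TFvW"),
                              kin_nad = kinetic_config("GGA"),
                              reference_energies = NULL) {
  stopifnot(length(configs) >= 1)
  grid <- build_grid(configs[[1]]$cell, cutoff)
  pre <- lapply(configs, function(geom) {
    at <- geometry_to_atoms(geom, role = "QM")
    v_qm <- qm_ionic_potential(at, grid)
    st <- minimize_ofdft(v_qm, at$n_electrons, kin_add,
                         init = scalar_field(grid,
                                             .atomic_guess(at, grid,
                                                           at$n_electrons)),
                         tol = 1e-8 * length(at$N))
    sites <- geometry_to_sites(geom, model, role = "MM")
    mu_ref <- isolated_mm_reference(sites, geom$cell, model$thole_a)
    Eq <- qm_field_at_mm_sites(st$density, v_qm, sites)
    dip <- solve_induced_dipoles(sites, Eq, geom$cell, model$thole_a)
    dip <- lapply(seq_along(dip), function(k)
      induced_dipole(k, dip[[k]]$mu, mu_ref[[k]]$mu_ref))
    eii <- .ion_ion_energies(at, sites, grid)
    e_mm <- mm_internal_energy(sites, dip, NULL, geom$cell,
                               model$thole_a)$total
    e_mm_iso <- mm_internal_energy(sites, mu_ref, NULL, geom$cell,
                                   model$thole_a)$total
    list(geom = geom, rho_qm = st$density, v_qm = v_qm, sites = sites,
         dipoles = dip, e_const = eii$qm_mm + e_mm - e_mm_iso)
  })
  structure(list(grid = grid, model = model, kin_nad = kin_nad,
                 configs = pre, reference = reference_energies),
            class = "dfq_fit_problem")
}

# model interaction energy (kcal/mol) of one precomputed configuration for
# a given width set
.fit_config_energy <- function(problem, cfg, widths) {
  sites <- lapply(cfg$sites, function(s) {
    s$sigma_q <- widths[[paste0("sigma_q_", s$element)]]
    s$sigma_mu <- widths[[paste0("sigma_mu_", s$element)]]
    s
  })
  rho_mm <- assemble_mm_density(sites, cfg$dipoles, problem$grid)
  v_mm <- mm_ionic_potential(sites, problem$grid)
  nad <- nonadditive_energy(cfg$rho_qm, rho_mm, cfg$v_qm, v_mm,
                            problem$kin_nad)
  ha_to_kcal(nad$total_nad + cfg$e_const)
}

#' Model interaction energies for a width vector
#'
#' @param problem `dfq_fit_problem`
#' @param widths named vector with elements `sigma_q_O`, `sigma_q_H`,
#'   `sigma_mu_O`, `sigma_mu_H` (bohr)
#' @return numeric vector of interaction energies, kcal/mol
#' @export
fit_model_energies <- function(problem, widths) {
  widths <- as.list(widths)
  vapply(problem$configs, function(cfg)
    .fit_config_energy(problem, cfg, widths), numeric(1))
}

#' Fit the MM Gaussian widths to reference interaction energies
#'
#' Minimizes the sum of squared deviations between model and reference
#' interaction energies over the four water width parameters
#' (sigma_q and sigma_mu for O and H) by bounded Levenberg-Marquardt on
#' the residual vector (with a finite-difference Jacobian), which follows
#' the shallow valleys of weakly determined width directions far more
#' reliably than quasi-Newton steps on the squared objective.
#'
#' @param problem `dfq_fit_problem` with `reference` set (kcal/mol)
#' @param start named start vector (defaults: the model defaults)
#' @param lower,upper per-parameter bounds, bohr
#' @param maxit iteration cap for the optimizer
#' @return list with `par` (fitted widths), `residuals` (kcal/mol),
#'   `rmse`, `objective`, `start_objective`, `converged`, `message`
#' @export
fit_widths <- function(problem,
                       start = c(sigma_q_O = 1.2, sigma_q_H = 1.0,
                                 sigma_mu_O = 1.3, sigma_mu_H = 1.1),
                       lower = 0.55, upper = 3.0, maxit = 120) {
  stopifnot(inherits(problem, "dfq_fit_problem"))
  ref <- problem$reference
  if (is.null(ref)) stop("fit problem has no reference energies")
  stopifnot(all(is.finite(ref)),
            length(ref) == length(problem$configs))
  if (length(problem$configs) < length(start))
    stop("need at least as many configurations as fitted parameters")
  lower <- rep_len(lower, length(start))
  upper <- rep_len(upper, length(start))
  # grid resolvability bound on the widths
  lower <- pmax(lower, 1.5 * max(problem$grid$spacing))
  resid_fun <- function(p) {
    names(p) <- names(start)
    fit_model_energies(problem, p) - ref
  }
  f0 <- sum(resid_fun(unname(start))^2)
  opt <- minpack.lm::nls.lm(unname(start), lower = lower, upper = upper,
                            fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxit, ftol = 1e-12, ptol = 1e-10))
  par <- opt$par
  names(par) <- names(start)
  res <- resid_fun(par)
  list(par = par, residuals = res,
       rmse = sqrt(mean(res^2)), objective = sum(res^2),
       start_objective = f0,
       converged = opt$info %in% 1:4, message = opt$message)
}

#' Partition RMSE statistic for fragment-boundary errors
#'
#' For a cluster of n molecules split into k QM and n - k MM molecules,
#' every one of the choose(n, k) members of the k-th partition would
#' ideally give the same interaction energy.  The spread quantifies the
#' boundary error: the per-k RMSE about the member mean is regressed
#' through the origin on sqrt(choose(n, k)), and the average error per
#' QM/MM boundary is slope * sqrt(pi/2) (the half-normal mean-RMSE
#' relation).
#'
#' @param energies_by_k named list: element "k" holds the choose(n, k)
#'   member interaction energies (kcal/mol) of partition k
#' @param n cluster size
#' @param intercept allow an intercept in the regression (default FALSE:
#'   proportionality through the origin)
#' @return list with `rmse_per_k` (data.frame k, n_members, rmse),
#'   `slope`, `error_per_boundary` (kcal/mol)
#' @export
partition_rmse <- function(energies_by_k, n, intercept = FALSE) {
  ks <- as.integer(names(energies_by_k))
  stopifnot(!any(is.na(ks)), all(ks >= 0), all(ks <= n))
  tab <- data.frame(k = ks,
                    n_members = vapply(energies_by_k, length, integer(1)))
  for (i in seq_along(ks)) {
    if (tab$n_members[i] != choose(n, ks[i]))
      stop("partition k = ", ks[i], " has ", tab$n_members[i],
           " members; expected choose(", n, ", ", ks[i], ") = ",
           choose(n, ks[i]))
  }
  tab$rmse <- vapply(energies_by_k, function(e) {
    if (length(e) < 2) return(NA_real_)
    sqrt(mean((e - mean(e))^2))
  }, numeric(1))
  fitdat <- tab[!is.na(tab$rmse), , drop = FALSE]
  x <- sqrt(choose(n, fitdat$k))
  y <- fitdat$rmse
  if (intercept) {
    co <- stats::coef(stats::lm(y ~ x))
    slope <- unname(co[2])
  } else {
    slope <- sum(x * y) / sum(x^2)
  }
  list(rmse_per_k = tab, slope = slope,
       error_per_boundary = slope * sqrt(pi / 2))
}
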