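#' @title Mutual-polarization QM/MM driver
#' @description Outer self-consistency loop: assemble the MM electron
#'   density from the current induced dipoles, minimize each QM subsystem
#'   density in its embedding potential, evaluate the QM electric field at
#'   the MM sites, re-solve the induced dipoles (with damped mixing), and
#'   repeat until both the total energy and the QM density are stationary.
#' @name scf_driver
NULL

#' SCF control parameters
#'
#' @param tol_energy outer-loop energy threshold, Ha per atom
#' @param tol_density L2 threshold on the QM density change,
#'   electrons (sqrt(int drho^2 dr))
#' @param tol_inner inner orbital-free minimizer threshold, Ha per atom
#' @param max_outer outer iteration cap
#' @param max_inner inner iteration cap
#' @param mix damping factor on the dipole update (1 = no damping)
#' @return list of class `dfq_scf_config`
#' @export
scf_config <- function(tol_energy = 1e-8, tol_density = 1e-6,
                       tol_inner = 1e-8, max_outer = 40, max_inner = 600,
                       mix = 0.8) {
  structure(list(tol_energy = tol_energy, tol_density = tol_density,
                 tol_inner = tol_inner, max_outer = max_outer,
                 max_inner = max_inner, mix = mix),
            class = "dfq_scf_config")
}

#' Assemble a QM/MM system from a geometry
#'
#' QM-role fragments become orbital-free QM subsystems (one per fragment by
#' default); MM-role atoms become polarizable force-field sites.
#'
#' @param geom `dfq_geometry` with a cell and QM/MM roles
#' @param cutoff grid energy cutoff, Ha
#' @param model `dfq_mm_model` force-field parameters
#' @param kin_add additive kinetic functional (`dfq_kinetic_config`,
#'   vW-containing)
#' @param kin_nad nonadditive kinetic functional
#' @param scf `dfq_scf_config`
#' @param group_qm "per-fragment" (each QM molecule its own subsystem) or
#'   "together" (one QM subsystem)
#' @param polarize solve induced dipoles (FALSE = charge-only mode: the MM
#'   density carries permanent charges only)
#' @param include_kinetic,include_xc nonadditive-term switches (diagnostics)
#' @return object of class `dfq_qmmm_system`
#' @export
qmmm_system <- function(geom, cutoff = 20, model = mm_model(),
                        kin_add = kinetic_config("TFvW"),
                        kin_nad = kinetic_config("GGA"),
                        scf = scf_config(),
                        group_qm = c("per-fragment", "together"),
                        polarize = TRUE,
                        include_kinetic = TRUE, include_xc = TRUE) {
  stopifnot(inherits(geom, "dfq_geometry"))
  if (is.null(geom$cell)) stop("geometry has no simulation cell")
  group_qm <- match.arg(group_qm)
  np <- nrow(geom$positions)
  if (np > 1) {
    for (i in seq_len(np - 1)) {
      dr <- .min_image(geom$cell,
                       sweep(geom$positions[(i + 1):np, , drop = FALSE], 2,
                             geom$positions[i, ], `-`))
      if (min(sqrt(rowSums(dr^2))) < 0.5)
        stop("atoms closer than 0.5 bohr in the input geometry")
    }
  }
  structure(list(geometry = geom, cutoff = cutoff, model = model,
                 kin_add = kin_add, kin_nad = kin_nad, scf = scf,
                 group_qm = group_qm, polarize = polarize,
                 include_kinetic = include_kinetic, include_xc = include_xc),
            class = "dfq_qmmm_system")
}

# split QM atoms into subsystems according to the grouping policy
.qm_subsystem_atoms <- function(system) {
  geom <- system$geometry
  qm_frags <- sort(unique(geom$fragment[geom$role == "QM"]))
  if (length(qm_frags) == 0) return(list())
  if (system$group_qm == "together") {
    return(list(geometry_to_atoms(geom, role = "QM")))
  }
  lapply(qm_frags, function(fr) {
    sub <- geom
    sub$role <- ifelse(geom$fragment == fr & geom$role == "QM", "QM", "MM")
    geometry_to_atoms(sub, role = "QM")
  })
}

# grid-based ion-ion energies with Gaussian-smeared cores.
# Returns QM-QM (self-interaction removed) and QM-MM cross terms.
.ion_ion_energies <- function(qm_atoms_all, mm_sites, grid) {
  e_qq <- 0; e_cross <- 0
  if (length(qm_atoms_all$N) > 0) {
    rho_qm_ion <- .ionic_charge_density(qm_atoms_all$positions,
                                        qm_atoms_all$N,
                                        qm_atoms_all$sigma_core, grid)
    phi_qm_ion <- solve_hartree(rho_qm_ion)
    e_qq <- 0.5 * sum(rho_qm_ion$values * phi_qm_ion$values) * grid$voxel -
      .ionic_self_energy(qm_atoms_all$N, qm_atoms_all$sigma_core)
    if (length(mm_sites) > 0) {
      rho_mm_ion <- .ionic_charge_density(lapply(mm_sites, `[[`, "position"),
                                          vapply(mm_sites, `[[`, numeric(1), "N"),
                                          vapply(mm_sites, `[[`, numeric(1),
                                                 "sigma_core"), grid)
      e_cross <- sum(rho_mm_ion$values * phi_qm_ion$values) * grid$voxel
    }
  }
  list(qm_qm = e_qq, qm_mm = e_cross)
}

# full total-energy bookkeeping for the current state
.total_energy <- function(system, grid, qm_states, qm_atoms_list, v_ion_list,
                          mm_sites, dipoles, mu_ref) {
  g <- grid
  kin_nad <- if (system$include_kinetic) system$kin_nad else NULL
  n_qm <- length(qm_states)
  rho_list <- lapply(qm_states, function(s) s$density$values)
  rho_qm_all <- Reduce(`+`, rho_list, array(0, dim = g$shape))
  has_mm <- length(mm_sites) > 0
  rho_mm <- if (has_mm) assemble_mm_density(mm_sites, dipoles, g) else
    scalar_field(g, 0)
  rho_all <- rho_qm_all + rho_mm$values
  # additive QM pieces
  e_add <- 0
  sl_I <- vector("list", n_qm)
  for (i in seq_len(n_qm)) {
    st <- qm_states[[i]]
    sl_I[[i]] <- .sl_combined(g, rho_list[[i]], kin_cfg = kin_nad,
                              with_xc = FALSE, need_potential = FALSE)
    phiI <- .ifftn_re(sl_I[[i]]$rho_hat * g$coulG)
    e_add <- e_add + st$parts$T_TF + st$parts$T_vW +
      0.5 * sum(rho_list[[i]] * phiI) * g$voxel +
      sum(rho_list[[i]] * v_ion_list[[i]]$values) * g$voxel
  }
  # xc: Exc[rho_all] - Exc[rho_MM] (MM internal xc replaced by the FF)
  sl_all <- .sl_combined(g, rho_all, kin_cfg = kin_nad,
                         with_xc = system$include_xc, need_potential = FALSE)
  sl_mm <- if (has_mm)
    .sl_combined(g, rho_mm$values, kin_cfg = kin_nad,
                 with_xc = system$include_xc, need_potential = FALSE)
    else list(e_kin = 0, e_xc = 0, rho_hat = array(0i, dim = g$shape))
  e_xc_tot <- sl_all$e_xc - sl_mm$e_xc
  # nonadditive kinetic: F[rho_all] - sum_I F[rho_I] - F[rho_MM]
  t_nad <- if (system$include_kinetic)
    sl_all$e_kin - sum(vapply(sl_I, `[[`, numeric(1), "e_kin")) - sl_mm$e_kin
    else 0
  # cross electrostatics among QM subsystems
  e_cross_qm <- 0
  if (n_qm > 1) {
    for (i in seq_len(n_qm - 1)) {
      phiI <- .ifftn_re(sl_I[[i]]$rho_hat * g$coulG)
      for (j in (i + 1):n_qm) {
        e_cross_qm <- e_cross_qm +
          sum(rho_list[[j]] * phiI) * g$voxel +
          sum(rho_list[[j]] * v_ion_list[[i]]$values) * g$voxel +
          sum(rho_list[[i]] * v_ion_list[[j]]$values) * g$voxel
      }
    }
  }
  # QM-MM cross electrostatics
  e_cross_mm <- 0; v_mm <- NULL
  if (has_mm) {
    phi_mm <- .ifftn_re(sl_mm$rho_hat * g$coulG)
    v_mm <- mm_ionic_potential(mm_sites, g)
    v_ion_qm_all <- Reduce(`+`, lapply(v_ion_list, `[[`, "values"),
                           array(0, dim = g$shape))
    e_cross_mm <- sum(rho_qm_all * phi_mm) * g$voxel +
      sum(rho_mm$values * v_ion_qm_all) * g$voxel +
      sum(rho_qm_all * v_mm$values) * g$voxel
  }
  # ion-ion
  qm_atoms_all <- .merge_atoms(qm_atoms_list)
  eii <- .ion_ion_energies(qm_atoms_all, mm_sites, g)
  # MM internal force-field energy (QM field excluded: it enters through
  # the density cross terms above)
  e_mm <- 0
  if (has_mm) {
    mm_en <- mm_internal_energy(mm_sites, dipoles, NULL,
                                system$geometry$cell, system$model$thole_a)
    e_mm <- mm_en$total
  }
  total <- e_add + e_xc_tot + t_nad + e_cross_qm + e_cross_mm +
    eii$qm_qm + eii$qm_mm + e_mm
  list(total = total,
       breakdown = list(E_add_QM = e_add, E_xc_total = e_xc_tot,
                        T_s_nad = t_nad, E_cross_QMQM = e_cross_qm,
                        E_cross_QMMM = e_cross_mm, E_ii_QMQM = eii$qm_qm,
                        E_ii_QMMM = eii$qm_mm, E_MM_internal = e_mm,
                        E_total = total))
}

.merge_atoms <- function(atoms_list) {
  if (length(atoms_list) == 0)
    return(list(positions = list(), elements = character(0), N = numeric(0),
                sigma_core = numeric(0), n_electrons = 0))
  list(positions = do.call(c, lapply(atoms_list, `[[`, "positions")),
       elements = do.call(c, lapply(atoms_list, `[[`, "elements")),
       N = do.call(c, lapply(atoms_list, `[[`, "N")),
       sigma_core = do.call(c, lapply(atoms_list, `[[`, "sigma_core")),
       n_electrons = sum(vapply(atoms_list, `[[`, numeric(1), "n_electrons")))
}

#' Run the mutual-polarization QM/MM self-consistency loop
#'
#' @param system `dfq_qmmm_system`
#' @param grid optional prebuilt `dfq_grid` (shared across runs that will
#'   be compared; built from the system cell and cutoff when NULL)
#' @param verbose print one line per outer iteration
#' @return object of class `dfq_qmmm_result`: `qm` (list of `dfq_qm_state`),
#'   `mm_sites`, `dipoles`, `mu_ref`, `energy` (total, Ha), `breakdown`,
#'   `trace` (data.frame: iteration, energy, dE, d_rho, max_dmu),
#'   `converged`, `grid`, `system`
#' @export
run_qmmm <- function(system, grid = NULL, verbose = FALSE) {
  stopifnot(inherits(system, "dfq_qmmm_system"))
  geom <- system$geometry
  if (is.null(grid)) grid <- build_grid(geom$cell, system$cutoff)
  scf <- system$scf
  n_atoms <- nrow(geom$positions)
  atoms_list <- .qm_subsystem_atoms(system)
  n_qm <- length(atoms_list)
  v_ion_list <- lapply(atoms_list, qm_ionic_potential, grid = grid)
  mm_sites <- geometry_to_sites(geom, system$model, role = "MM")
  has_mm <- length(mm_sites) > 0
  # isolated-MM reference dipoles mu'
  mu_ref <- if (has_mm && system$polarize)
    isolated_mm_reference(mm_sites, geom$cell, system$model$thole_a)
  else lapply(seq_along(mm_sites), induced_dipole)
  dipoles <- mu_ref
  if (!system$polarize)
    dipoles <- lapply(seq_along(mm_sites), induced_dipole)
  # initial QM densities
  qm_states <- lapply(seq_len(n_qm), function(i) {
    list(density = scalar_field(grid, .atomic_guess(atoms_list[[i]], grid,
                                                    atoms_list[[i]]$n_electrons)),
         parts = list(T_TF = 0, T_vW = 0))
  })
  v_mm <- if (has_mm) mm_ionic_potential(mm_sites, grid) else
    scalar_field(grid, 0)
  E_prev <- NA_real_
  trace <- data.frame(iteration = integer(0), energy = numeric(0),
                      dE = numeric(0), d_rho = numeric(0),
                      max_dmu = numeric(0))
  converged <- FALSE
  for (it in seq_len(scf$max_outer)) {
    rho_mm <- if (has_mm) assemble_mm_density(mm_sites, dipoles, grid) else
      NULL
    # minimize each QM subsystem in its frozen environment
    d_rho <- 0
    for (i in seq_len(n_qm)) {
      rho_env_vals <- Reduce(`+`,
                             lapply(qm_states[-i], function(s) s$density$values),
                             if (has_mm) rho_mm$values else
                               array(0, dim = grid$shape))
      v_env_vals <- Reduce(`+`,
                           lapply(v_ion_list[-i], `[[`, "values"),
                           v_mm$values)
      have_env <- has_mm || n_qm > 1
      emb <- if (have_env)
        embedding_environment(scalar_field(grid, rho_env_vals),
                              scalar_field(grid, v_env_vals),
                              system$kin_nad,
                              include_kinetic = system$include_kinetic,
                              include_xc = system$include_xc)
      else NULL
      init <- if (it == 1)
        scalar_field(grid, qm_states[[i]]$density$values) else
          qm_states[[i]]$density
      st <- minimize_ofdft(v_ion_list[[i]],
                           atoms_list[[i]]$n_electrons,
                           system$kin_add, init = init, embedding = emb,
                           tol = scf$tol_inner *
                             length(atoms_list[[i]]$N),
                           max_iter = scf$max_inner)
      d_rho <- d_rho + sqrt(sum((st$density$values -
                                   qm_states[[i]]$density$values)^2) *
                              grid$voxel)
      qm_states[[i]] <- st
    }
    # QM field at MM sites and dipole update
    max_dmu <- 0
    if (has_mm && system$polarize) {
      rho_qm_all <- Reduce(`+`, lapply(qm_states, function(s) s$density$values),
                           array(0, dim = grid$shape))
      v_ion_all <- Reduce(`+`, lapply(v_ion_list, `[[`, "values"),
                          array(0, dim = grid$shape))
      Eqm <- qm_field_at_mm_sites(scalar_field(grid, rho_qm_all),
                                  scalar_field(grid, v_ion_all), mm_sites)
      new_d <- solve_induced_dipoles(mm_sites, Eqm, geom$cell,
                                     system$model$thole_a)
      mixed <- lapply(seq_along(mm_sites), function(k) {
        mu <- (1 - scf$mix) * dipoles[[k]]$mu + scf$mix * new_d[[k]]$mu
        induced_dipole(k, mu, mu_ref[[k]]$mu_ref)
      })
      max_dmu <- max(vapply(seq_along(mm_sites), function(k)
        max(abs(mixed[[k]]$mu - dipoles[[k]]$mu)), numeric(1)), 0)
      dipoles <- mixed
    }
    en <- .total_energy(system, grid, qm_states, atoms_list, v_ion_list,
                        mm_sites, dipoles, mu_ref)
    dE <- if (is.na(E_prev)) NA_real_ else en$total - E_prev
    trace <- rbind(trace, data.frame(iteration = it, energy = en$total,
                                     dE = ifelse(is.na(dE), 0, dE),
                                     d_rho = d_rho, max_dmu = max_dmu))
    if (verbose)
      message(sprintf("SCF %2d  E = %18.10f  dE = %10.3e  |drho| = %9.3e  |dmu| = %9.3e",
                      it, en$total, ifelse(is.na(dE), 0, dE), d_rho, max_dmu))
    if (!is.na(dE) &&
        abs(dE) < scf$tol_energy * n_atoms &&
        d_rho < scf$tol_density &&
        (!has_mm || !system$polarize || max_dmu < 1e-6)) {
      converged <- TRUE
      E_prev <- en$total
      break
    }
    # oscillation detector: alternating-sign energy steps of growing size
    ne <- nrow(trace)
    if (ne >= 5) {
      d1 <- trace$dE[ne]; d2 <- trace$dE[ne - 1]; d3 <- trace$dE[ne - 2]
      if (d1 * d2 < 0 && d2 * d3 < 0 && abs(d1) > abs(d3) &&
          abs(d1) > 1e-4 * (1 + abs(en$total)))
        stop(structure(class = c("dfq_oscillation", "error", "condition"),
                       list(message = "outer SCF energy is cycling (mutual-polarization oscillation); reduce the mixing factor",
                            call = sys.call(-1), trace = trace)))
    }
    E_prev <- en$total
    # static embedding (no MM, or rigid charges): nothing in the
    # environment responds, so energy stationarity of the variational
    # inner minimizer suffices
    if ((!has_mm || !system$polarize) && it >= 2 && !is.na(dE) &&
        abs(dE) < scf$tol_energy * n_atoms) {
      converged <- TRUE
      E_prev <- en$total
      break
    }
  }
  en <- .total_energy(system, grid, qm_states, atoms_list, v_ion_list,
                      mm_sites, dipoles, mu_ref)
  structure(list(qm = qm_states, mm_sites = mm_sites, dipoles = dipoles,
                 mu_ref = mu_ref, energy = en$total,
                 breakdown = en$breakdown, trace = trace,
                 converged = converged, grid = grid, system = system),
            class = "dfq_qmmm_result")
}

#' @export
print.dfq_qmmm_result <- function(x, ...) {
  cat(sprintf("dfq_qmmm_result: E = %.8f Ha (%s, %d outer iterations)\n",
              x$energy, if (x$converged) "converged" else "NOT converged",
              nrow(x$trace)))
  invisible(x)
}

#' Internal energy of an isolated MM subsystem
#'
#' Force-field energy of the MM geometry alone, at its own converged
#' dipoles (the self-energy correction is zero there by construction).
#'
#' @param system `dfq_qmmm_system` (its MM part is used)
#' @return energy in Ha
#' @export
isolated_mm_energy <- function(system) {
  geom <- system$geometry
  mm_sites <- geometry_to_sites(geom, system$model, role = "MM")
  if (length(mm_sites) == 0) return(0)
  d <- if (system$polarize)
    isolated_mm_reference(mm_sites, geom$cell, system$model$thole_a)
  else lapply(seq_along(mm_sites), induced_dipole)
  mm_internal_energy(mm_sites, d, NULL, geom$cell,
                     system$model$thole_a)$total
}

#' Interaction energy of a QM/MM state
#'
#' E_int = E_total - sum of isolated-fragment energies, in kcal/mol.
#'
#' @param result converged `dfq_qmmm_result` of the full system
#' @param isolated_qm `dfq_qmmm_result` or list of them: each QM fragment
#'   alone (same cell, grid and functional configuration)
#' @param isolated_mm_energy_ha isolated-MM force-field energy in Ha
#'   (see `isolated_mm_energy`)
#' @return interaction energy in kcal/mol
#' @export
interaction_energy <- function(result, isolated_qm,
                               isolated_mm_energy_ha = 0) {
  stopifnot(inherits(result, "dfq_qmmm_result"))
  if (inherits(isolated_qm, "dfq_qmmm_result"))
    isolated_qm <- list(isolated_qm)
  for (iso in isolated_qm) {
    if (!identical(iso$grid$shape, result$grid$shape) ||
        !isTRUE(all.equal(iso$grid$cell$lattice,
                          result$grid$cell$lattice)) ||
        !identical(iso$system$kin_add$family,
                   result$system$kin_add$family) ||
        !identical(iso$system$kin_nad, result$system$kin_nad))
      stop("isolated-fragment run does not share the cell/grid/functional configuration of the full run")
  }
  e_iso <- sum(vapply(isolated_qm, `[[`, numeric(1), "energy"))
  ha_to_kcal(result$energy - e_iso - isolated_mm_energy_ha)
}

#' Convergence scan over the QM subsystem size
#'
#' Promotes the n nearest solvent molecules (by the supplied ordering) to
#' the QM level and records the solute-environment interaction energy for
#' each size, in both polarizable and charge-only modes.
#'
#' @param base_system `dfq_qmmm_system` whose geometry has one QM solute
#'   fragment and MM solvent fragments
#' @param ordering integer vector of solvent fragment ids, sorted by
#'   distance to the solute (nearest first); must cover all MM fragments
#' @param sizes integer vector of QM solvent counts to scan
#' @param convergence_band width (kcal/mol) of the target window used to
#'   flag convergence of the scan (default 2)
#' @param verbose print progress
#' @return data.frame with columns `n_qm_solvent`, `E_int_polarizable`,
#'   `E_int_charge_only` (kcal/mol), and attribute `converged_within_band`
#' @export
qm_size_scan <- function(base_system, ordering, sizes,
                         convergence_band = 2, verbose = FALSE) {
  geom <- base_system$geometry
  solute <- sort(unique(geom$fragment[geom$role == "QM"]))
  solvent <- sort(unique(geom$fragment[geom$role == "MM"]))
  if (!setequal(ordering, solvent))
    stop("ordering must list every MM solvent fragment exactly once")
  grid <- build_grid(geom$cell, base_system$cutoff)
  one <- function(n_qm, polarize) {
    qm_frags <- c(solute, ordering[seq_len(n_qm)])
    g2 <- set_partition_roles(geom, qm_frags)
    sys2 <- base_system
    sys2$geometry <- g2
    sys2$polarize <- polarize
    full <- run_qmmm(sys2, grid = grid)
    isos <- lapply(qm_frags, function(fr) {
      gi <- g2
      keep <- gi$fragment == fr
      gi$elements <- gi$elements[keep]
      gi$positions <- gi$positions[keep, , drop = FALSE]
      gi$fragment <- gi$fragment[keep]
      gi$role <- rep("QM", sum(keep))
      si <- sys2; si$geometry <- gi
      run_qmmm(si, grid = grid)
    })
    # isolated MM part of this partition
    smm <- sys2
    interaction_energy(full, isos, isolated_mm_energy(smm))
  }
  res <- data.frame(n_qm_solvent = sizes,
                    E_int_polarizable = NA_real_,
                    E_int_charge_only = NA_real_)
  for (k in seq_along(sizes)) {
    if (verbose) message("qm_size_scan: size ", sizes[k])
    res$E_int_polarizable[k] <- one(sizes[k], TRUE)
    res$E_int_charge_only[k] <- one(sizes[k], FALSE)
  }
  nk <- nrow(res)
  attr(res, "converged_within_band") <- nk >= 2 &&
    abs(res$E_int_polarizable[nk] - res$E_int_polarizable[nk - 1]) <=
    convergence_band
  res
}
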