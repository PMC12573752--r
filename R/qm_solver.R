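#' @title Orbital-free DFT ground-state solver
#' @description Minimizes T_s[rho] + E_H[rho] + E_xc[rho] + int v_ext rho
#'   (plus, when embedded, the density-dependent part of the nonadditive
#'   interaction with a frozen environment density) over rho = phi^2 with
#'   fixed electron count, by projected nonlinear conjugate gradient on phi
#'   with norm-preserving curvilinear (great-circle) steps.
#' @name qm_solver
NULL

#' Extract the QM atoms of a geometry
#'
#' @param geom `dfq_geometry`
#' @param role role filter ("QM" by default, NULL for all atoms)
#' @return list with `positions` (list of bohr triples), `elements`,
#'   `N` (valence counts), `sigma_core` (bohr) and `n_electrons`
#' @export
geometry_to_atoms <- function(geom, role = "QM") {
  keep <- if (is.null(role)) seq_along(geom$elements) else
    which(geom$role == role)
  el <- geom$elements[keep]
  ed <- lapply(el, element_defaults)
  list(positions = lapply(keep, function(i) geom$positions[i, ]),
       elements = el,
       N = vapply(ed, `[[`, numeric(1), "N"),
       sigma_core = vapply(ed, `[[`, numeric(1), "sigma_core"),
       fragment = geom$fragment[keep],
       n_electrons = sum(vapply(ed, `[[`, numeric(1), "N")))
}

#' Ionic local potential of a set of QM atoms
#'
#' Superposition of per-atom local pseudopotentials
#' v_loc(r) = -N erf(r/(sqrt(2) sigma_core))/r, with the G = 0 component
#' removed (background convention).
#'
#' @param atoms as returned by `geometry_to_atoms`
#' @param grid `dfq_grid`
#' @return `dfq_field` (Ha per electron)
#' @export
qm_ionic_potential <- function(atoms, grid) {
  if (length(atoms$N) == 0) return(scalar_field(grid, 0))
  .ionic_potential(atoms$positions, atoms$N, atoms$sigma_core, grid)
}

# initial density: superposed atomic Gaussians carrying the valence counts
.atomic_guess <- function(atoms, grid, n_electrons) {
  if (length(atoms$N) == 0) {
    v <- array(n_electrons / grid$volume, dim = grid$shape)
    return(v)
  }
  cG <- array(0i, dim = grid$shape)
  for (i in seq_along(atoms$N)) {
    cG <- cG + .gaussian_coeff(grid, atoms$positions[[i]],
                               1.5 * atoms$sigma_core[i], atoms$N[i])
  }
  v <- pmax(Re(stats::fft(cG, inverse = TRUE)), 1e-10)
  v * n_electrons / (sum(v) * grid$voxel)
}

#' Embedding environment for the orbital-free solver
#'
#' Packages the frozen environment needed by `minimize_ofdft`: the
#' environment electron density, its ionic potential, and the nonadditive
#' functional configuration.  The Hartree potential of the environment and
#' the constant environment functional terms are precomputed here.
#'
#' @param rho_env `dfq_field`, frozen environment electron density
#' @param v_env `dfq_field`, environment ionic potential
#' @param cfg_nad `dfq_kinetic_config` for the nonadditive kinetic term
#' @param include_kinetic include the nonadditive kinetic term (disabling it
#'   reproduces the charge spill-out pathology)
#' @param include_xc include the nonadditive exchange-correlation term
#' @return list used as the `embedding` argument of `minimize_ofdft`
#' @export
embedding_environment <- function(rho_env, v_env,
                                  cfg_nad = kinetic_config("GGA"),
                                  include_kinetic = TRUE, include_xc = TRUE) {
  grid <- rho_env$grid
  phi_env <- solve_hartree(rho_env)
  v_static <- v_env$values + phi_env$values
  env_sl <- .sl_combined(grid, rho_env$values,
                         kin_cfg = if (include_kinetic) cfg_nad else NULL,
                         with_xc = include_xc)
  list(rho_env = rho_env$values, rho_env_hat = env_sl$rho_hat,
       v_static = v_static, cfg_nad = cfg_nad,
       include_kinetic = include_kinetic, include_xc = include_xc,
       e_env_kin = env_sl$e_kin, e_env_xc = env_sl$e_xc)
}

# energy + gradient of the phi-parametrized objective
.of_eval <- function(phi, grid, v_ext, cfg, emb, need_grad = TRUE,
                     with_hartree = TRUE, with_xc = TRUE) {
  rho <- phi^2
  rho_hat <- .fftn(rho)
  if (with_hartree) {
    phi_H <- .ifftn_re(rho_hat * grid$coulG)
    e_H <- 0.5 * sum(rho * phi_H) * grid$voxel
  } else {
    phi_H <- 0
    e_H <- 0
  }
  e_ext <- sum(rho * v_ext) * grid$voxel
  # additive kinetic: TF (or none) pointwise + lambda vW via phi
  lam <- switch(cfg$family, vW = 1, TFvW = cfg$lambda, TF = 0, GGA = 0)
  use_tf <- cfg$family %in% c("TF", "TFvW")
  if (cfg$family == "GGA")
    stop("the additive kinetic functional of the OF solver must contain a vW component (family vW or TFvW)")
  rc <- pmax(rho, 1e-12)
  e_tf <- if (use_tf) C_TF * sum(rc^(5 / 3)) * grid$voxel else 0
  v_tf <- if (use_tf) (5 / 3) * C_TF * rc^(2 / 3) else 0
  lap_phi <- .lap_array(grid, phi)
  e_vw <- -0.5 * sum(phi * lap_phi) * grid$voxel
  if (is.null(emb)) {
    if (with_xc) {
      sl <- .sl_combined(grid, rho, kin_cfg = NULL, with_xc = TRUE,
                         rho_hat = rho_hat)
      e_xc <- sl$e_xc
      v_sl <- sl$v
    } else {
      e_xc <- 0
      v_sl <- 0
    }
    v_other <- v_tf + phi_H + v_ext + v_sl
    e_nad <- 0
  } else {
    rho_tot <- rho + emb$rho_env
    tot_hat <- rho_hat + emb$rho_env_hat
    kin_nad <- if (emb$include_kinetic) emb$cfg_nad else NULL
    slt <- .sl_combined(grid, rho_tot, kin_cfg = kin_nad,
                        with_xc = emb$include_xc, rho_hat = tot_hat)
    # subtract the additive-on-rho parts of the nonadditive difference;
    # additive xc of the QM density cancels against -Exc[rho] in the
    # nonadditive term, so only Exc[rho_tot] survives when xc is embedded
    sls <- .sl_combined(grid, rho, kin_cfg = kin_nad,
                        with_xc = !emb$include_xc, kin_scale = -1,
                        rho_hat = rho_hat)
    e_xc <- if (emb$include_xc) slt$e_xc - emb$e_env_xc else sls$e_xc
    e_nad_kin <- if (emb$include_kinetic)
      slt$e_kin + sls$e_kin - emb$e_env_kin else 0
    e_emb_stat <- sum(rho * emb$v_static) * grid$voxel
    e_nad <- e_nad_kin + e_emb_stat
    v_other <- v_tf + phi_H + v_ext + slt$v + sls$v + emb$v_static
  }
  energy <- e_tf + lam * e_vw + e_H + e_xc + e_ext + e_nad
  out <- list(energy = energy,
              parts = list(T_TF = e_tf, T_vW = lam * e_vw, E_H = e_H,
                           E_xc = e_xc, E_ext = e_ext, E_emb = e_nad))
  if (need_grad) {
    out$grad <- 2 * phi * v_other - lam * lap_phi
    out$v_other <- v_other
  }
  out
}

#' Minimize the orbital-free energy functional
#'
#' Projected nonlinear conjugate gradient on phi = sqrt(rho) with spherical
#' (norm-preserving) line steps; the electron count is conserved exactly at
#' every iterate.  The line-search energy sequence is non-increasing.
#'
#' @param v_ext `dfq_field`, external (ionic plus any static) potential
#' @param n_electrons electron count (> 0)
#' @param cfg `dfq_kinetic_config` for the additive kinetic functional;
#'   must contain a von Weizsacker component ("vW" or "TFvW")
#' @param init optional `dfq_field` with a starting density
#' @param embedding optional environment from `embedding_environment`
#' @param tol convergence threshold on the energy change per step (Ha);
#'   the conventional choice is 1e-8 Ha per atom
#' @param max_iter iteration cap
#' @return object of class `dfq_qm_state`: `density` (`dfq_field`), `phi`,
#'   `energy` (minimized objective, Ha), `parts` (additive components),
#'   `mu` (chemical potential estimate), `trace` (per-iteration energies),
#'   `converged`, `n_electrons`
#' @export
minimize_ofdft <- function(v_ext, n_electrons, cfg = kinetic_config("TFvW"),
                           init = NULL, embedding = NULL, tol = 1e-8,
                           max_iter = 500, with_hartree = TRUE,
                           with_xc = TRUE) {
  stopifnot(inherits(v_ext, "dfq_field"), n_electrons > 0)
  grid <- v_ext$grid
  vox <- grid$voxel
  rho0 <- if (is.null(init)) NULL else pmax(init$values, 1e-12)
  if (is.null(rho0))
    rho0 <- array(n_electrons / grid$volume, dim = grid$shape)
  phi <- sqrt(rho0)
  phi <- phi * sqrt(n_electrons / (sum(phi^2) * vox))
  st <- .of_eval(phi, grid, v_ext$values, cfg, embedding,
                 with_hartree = with_hartree, with_xc = with_xc)
  trace <- st$energy
  g_prev <- NULL; d <- NULL
  theta_t <- 0.05
  converged <- FALSE
  ip <- function(a, b) sum(a * b) * vox
  for (it in seq_len(max_iter)) {
    g <- st$grad
    g <- g - (ip(g, phi) / n_electrons) * phi      # project onto constraint
    if (!is.null(g_prev)) {
      beta <- max(0, ip(g, g - g_prev) / ip(g_prev, g_prev))
      d <- -g + beta * d
      d <- d - (ip(d, phi) / n_electrons) * phi
      if (ip(d, g) >= 0) d <- -g
    } else d <- -g
    g_prev <- g
    nd <- sqrt(ip(d, d))
    if (nd < 1e-14) { converged <- TRUE; break }
    dhat <- d * (sqrt(n_electrons) / nd)
    dE0 <- ip(g, dhat)                             # dE/dtheta at theta = 0
    E0 <- st$energy
    step <- function(theta) phi * cos(theta) + dhat * sin(theta)
    th <- theta_t
    st_t <- .of_eval(step(th), grid, v_ext$values, cfg, embedding,
                     need_grad = FALSE, with_hartree = with_hartree,
                     with_xc = with_xc)
    cquad <- (st_t$energy - E0 - dE0 * th) / th^2
    th_opt <- if (cquad > 0) -dE0 / (2 * cquad) else th * 2
    th_opt <- max(min(th_opt, 4 * th, pi / 2), 1e-8)
    best_th <- if (st_t$energy < E0) th else 0
    best_E <- min(st_t$energy, E0)
    st_o <- .of_eval(step(th_opt), grid, v_ext$values, cfg, embedding,
                     need_grad = FALSE, with_hartree = with_hartree,
                     with_xc = with_xc)
    if (st_o$energy < best_E) { best_E <- st_o$energy; best_th <- th_opt }
    k <- 0
    while (best_th == 0 && k < 12) {               # backtrack to a decrease
      th <- th / 4
      st_t <- .of_eval(step(th), grid, v_ext$values, cfg, embedding,
                       need_grad = FALSE, with_hartree = with_hartree,
                       with_xc = with_xc)
      if (st_t$energy < E0) { best_E <- st_t$energy; best_th <- th }
      k <- k + 1
    }
    if (best_th == 0) {                            # no descent found
      if (it > 1 && abs(trace[length(trace)] - trace[length(trace) - 1]) < tol)
        converged <- TRUE
      break
    }
    phi <- step(best_th)
    theta_t <- max(min(best_th, 0.2), 1e-4)
    st <- .of_eval(phi, grid, v_ext$values, cfg, embedding,
                   with_hartree = with_hartree, with_xc = with_xc)
    trace <- c(trace, st$energy)
    n <- length(trace)
    if (n >= 3 && abs(trace[n] - trace[n - 1]) < tol &&
        abs(trace[n - 1] - trace[n - 2]) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && max_iter > 50)
    stop(structure(class = c("dfq_nonconvergence", "error", "condition"),
                   list(message = paste0("orbital-free minimization did not ",
                                         "converge in ", max_iter,
                                         " iterations (last dE = ",
                                         format(abs(diff(utils::tail(trace, 2)))),
                                         " Ha)"),
                        call = sys.call(-1), trace = trace)))
  rho <- phi^2
  # chemical potential: density-weighted mean of delta E / delta rho
  lam <- switch(cfg$family, vW = 1, TFvW = cfg$lambda, 0)
  v_kin_vw <- -lam * .lap_array(grid, phi) / pmax(2 * phi, 1e-12) * 2
  vtot <- st$v_other + 0.5 * v_kin_vw
  mu <- sum(vtot * rho) / sum(rho)
  structure(list(density = scalar_field(grid, rho), phi = phi,
                 energy = st$energy, parts = st$parts, mu = mu,
                 trace = trace, converged = converged,
                 n_electrons = n_electrons),
            class = "dfq_qm_state")
}
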