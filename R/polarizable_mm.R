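#' @title Minimal polarizable force field
#' @description Three-site rigid water with fixed atomic point charges,
#'   isotropic atomic polarizabilities on O and H, Thole exponential damping
#'   between polarizable sites, 1-2/1-3 intramolecular permanent-field
#'   exclusions, and the dipole self-energy correction k_SE |mu - mu'|^2.
#'   Any self-consistent polarizable point-charge/point-dipole model
#'   exercises the same embedding machinery; this one is deliberately small.
#' @name polarizable_mm
NULL

#' Force-field parameter set for the built-in water model
#'
#' @param q_O,q_H permanent charges (e)
#' @param alpha_O,alpha_H isotropic polarizabilities (bohr^3)
#' @param thole_a Thole exponential damping factor (dimensionless);
#'   `Inf` disables damping
#' @param k_SE_O,k_SE_H dipole self-energy correction constants
#'   (Ha/(e bohr)^2)
#' @param sigma_q,sigma_mu named numeric vectors of Gaussian widths (bohr)
#'   per element; defaults from `element_defaults`
#' @return object of class `dfq_mm_model`
#' @export
mm_model <- function(q_O = -0.8476, q_H = 0.4238,
                     alpha_O = 8.84, alpha_H = 1.98,
                     thole_a = 0.39, k_SE_O = 0, k_SE_H = 0,
                     sigma_q = NULL, sigma_mu = NULL) {
  defq <- c(O = element_defaults("O")$sigma_q, H = element_defaults("H")$sigma_q)
  defm <- c(O = element_defaults("O")$sigma_mu, H = element_defaults("H")$sigma_mu)
  if (!is.null(sigma_q)) defq[names(sigma_q)] <- sigma_q
  if (!is.null(sigma_mu)) defm[names(sigma_mu)] <- sigma_mu
  structure(list(q = c(O = q_O, H = q_H),
                 alpha = c(O = alpha_O, H = alpha_H),
                 thole_a = thole_a,
                 k_SE = c(O = k_SE_O, H = k_SE_H),
                 sigma_q = defq, sigma_mu = defm),
            class = "dfq_mm_model")
}

#' Build MM sites from a geometry
#'
#' @param geom a `dfq_geometry` (see `read_xyz`); only atoms whose fragment
#'   role is "MM" are converted unless `role = NULL`
#' @param model `dfq_mm_model`
#' @param role role filter ("MM", "QM" or NULL for all atoms)
#' @return list of `dfq_mm_site` (each carrying its fragment id)
#' @export
geometry_to_sites <- function(geom, model = mm_model(), role = "MM") {
  keep <- if (is.null(role)) seq_along(geom$elements) else
    which(geom$role == role)
  lapply(keep, function(i) {
    el <- geom$elements[i]
    s <- mm_site(geom$positions[i, ], el,
                 q = model$q[[el]],
                 sigma_q = model$sigma_q[[el]],
                 sigma_mu = model$sigma_mu[[el]],
                 alpha = model$alpha[[el]],
                 k_SE = model$k_SE[[el]])
    s$fragment <- geom$fragment[i]
    s
  })
}

# minimum-image displacement vectors r_i - r_j (rows) for all pairs;
# returns list with matrices pos (n x 3) and function mi(vec)
.min_image <- function(cell, dr) {
  if (is.null(cell)) return(dr)
  f <- dr %*% cell$inv_lattice
  f <- f - round(f)
  f %*% cell$lattice
}

# pairwise damped interaction machinery shared by field and energy code.
# Returns, for each ordered pair (i, j), the field at i due to charge and
# dipole at j.  Exclusions: same nonzero fragment id.
.mm_pair_data <- function(sites, cell) {
  n <- length(sites)
  pos <- do.call(rbind, lapply(sites, `[[`, "position"))
  q <- vapply(sites, `[[`, numeric(1), "q")
  al <- vapply(sites, `[[`, numeric(1), "alpha")
  frag <- vapply(seq_along(sites), function(i) {
    f <- sites[[i]]$fragment
    if (is.null(f) || is.na(f)) -i else as.numeric(f)   # unique -> no exclusion
  }, numeric(1))
  list(n = n, pos = pos, q = q, alpha = al, frag = frag)
}

# Thole damping factors for a pair at distance r
.thole <- function(r, ai, aj, a) {
  if (!is.finite(a) || ai <= 0 || aj <= 0) return(c(l3 = 1, l5 = 1))
  u <- r / (ai * aj)^(1 / 6)
  au3 <- a * u^3
  e <- exp(-au3)
  c(l3 = 1 - e, l5 = 1 - (1 + au3) * e)
}

# permanent-charge field at every site (intramolecular pairs excluded)
.permanent_field <- function(pd, cell, thole_a) {
  E <- matrix(0, pd$n, 3)
  for (i in seq_len(pd$n)) {
    for (j in seq_len(pd$n)) {
      if (i == j || pd$frag[i] == pd$frag[j]) next
      dr <- .min_image(cell, matrix(pd$pos[i, ] - pd$pos[j, ], 1))
      r <- sqrt(sum(dr^2))
      lam <- .thole(r, pd$alpha[i], pd$alpha[j], thole_a)
      E[i, ] <- E[i, ] + lam["l3"] * pd$q[j] * dr / r^3
    }
  }
  E
}

# field at site i from dipole mu_j: T_ij mu_j with Thole damping
.dipole_field_one <- function(dr, r, mu, lam) {
  rr <- sum(dr * mu)
  (3 * lam["l5"] * rr * dr / r^2 - lam["l3"] * mu) / r^3
}

#' Solve the self-consistent induced dipoles
#'
#' Iterates mu_i = alpha_i (E_perm,i + E_ext,i + sum_j T_ij mu_j) with Thole
#' exponential damping and intramolecular permanent-field exclusions until
#' max |delta mu| < `tol`.  A growing iteration (polarization catastrophe)
#' aborts with an error naming the closest polarizable pair.
#'
#' @param sites list of `dfq_mm_site`
#' @param external_field n x 3 matrix of external fields at the sites
#'   (Ha/(e bohr); the physical electric field), or NULL for zero
#' @param cell `dfq_cell` for minimum-image distances, or NULL for open
#'   boundaries
#' @param thole_a damping factor (default 0.39; `Inf` disables damping)
#' @param tol convergence threshold on max |delta mu|, e bohr
#' @param max_iter iteration cap
#' @return list of `dfq_induced_dipole` (with `mu_ref` left zero)
#' @export
solve_induced_dipoles <- function(sites, external_field = NULL, cell = NULL,
                                  thole_a = 0.39, tol = 1e-8,
                                  max_iter = 500) {
  pd <- .mm_pair_data(sites, cell)
  if (is.null(external_field)) external_field <- matrix(0, pd$n, 3)
  external_field <- matrix(external_field, pd$n, 3)
  stopifnot(all(is.finite(external_field)))
  E0 <- .permanent_field(pd, cell, thole_a) + external_field
  mu <- matrix(0, pd$n, 3)
  pol <- which(pd$alpha > 0)
  if (length(pol) == 0)
    return(lapply(seq_len(pd$n), function(i) induced_dipole(i)))
  # undamped two-site instability: alpha_i alpha_j (2/r^3)^2 >= 1
  if (!is.finite(thole_a)) {
    for (a in seq_along(pol)) for (b in seq_along(pol)) {
      if (b <= a) next
      i <- pol[a]; j <- pol[b]
      dr <- .min_image(cell, matrix(pd$pos[i, ] - pd$pos[j, ], 1))
      r <- sqrt(sum(dr^2))
      if (r^6 <= 4 * pd$alpha[i] * pd$alpha[j])
        stop(sprintf(paste0("polarization catastrophe: undamped sites %d and ",
                            "%d at %.3f bohr are closer than the stability ",
                            "limit %.3f bohr"),
                     i, j, r, (4 * pd$alpha[i] * pd$alpha[j])^(1 / 6)))
    }
  }
  prev_d <- Inf; grow <- 0L
  for (it in seq_len(max_iter)) {
    Eind <- matrix(0, pd$n, 3)
    for (i in pol) {
      for (j in pol) {
        if (i == j) next
        dr <- .min_image(cell, matrix(pd$pos[i, ] - pd$pos[j, ], 1))
        r <- sqrt(sum(dr^2))
        lam <- .thole(r, pd$alpha[i], pd$alpha[j], thole_a)
        Eind[i, ] <- Eind[i, ] + .dipole_field_one(dr, r, mu[j, ], lam)
      }
    }
    mu_new <- mu
    mu_new[pol, ] <- pd$alpha[pol] * (E0[pol, , drop = FALSE] +
                                        Eind[pol, , drop = FALSE])
    d <- max(abs(mu_new - mu))
    mu <- 0.5 * (mu + mu_new)      # damped update for stability
    if (d < tol) break
    if (d > prev_d * (1 + 1e-12)) grow <- grow + 1L else grow <- 0L
    if (grow >= 10L || !all(is.finite(mu)) || max(abs(mu)) > 1e4) {
      pr <- .closest_polarizable_pair(pd, pol, cell)
      stop(sprintf(paste0("polarization catastrophe: induced dipoles diverge",
                          " (closest polarizable pair %d-%d at %.3f bohr)"),
                   pr[1], pr[2], pr[3]))
    }
    prev_d <- d
    if (it == max_iter)
      stop("induced-dipole iteration did not converge in ", max_iter,
           " steps (last delta ", format(d), ")")
  }
  lapply(seq_len(pd$n), function(i) induced_dipole(i, mu = mu[i, ]))
}

.closest_polarizable_pair <- function(pd, pol, cell) {
  best <- c(0, 0, Inf)
  for (a in seq_along(pol)) for (b in seq_along(pol)) {
    if (b <= a) next
    i <- pol[a]; j <- pol[b]
    dr <- .min_image(cell, matrix(pd$pos[i, ] - pd$pos[j, ], 1))
    r <- sqrt(sum(dr^2))
    if (r < best[3]) best <- c(i, j, r)
  }
  best
}

#' Classical internal energy of the MM subsystem
#'
#' Permanent-permanent electrostatics (minimum image, intramolecular pairs
#' excluded), induction energy -mu.(E_perm + E_ext) + |mu|^2/(2 alpha)
#' - (1/2) mu_i T_ij mu_j, and the self-energy correction
#' sum_i k_SE |mu_i - mu'_i|^2.  At the converged dipoles the induction part
#' equals -(1/2) sum mu . (E_perm + E_ext).
#'
#' @param sites list of `dfq_mm_site`
#' @param dipoles list of `dfq_induced_dipole` (mu_ref used for the
#'   self-energy correction)
#' @param external_field n x 3 matrix or NULL
#' @param cell `dfq_cell` or NULL
#' @param thole_a damping factor
#' @return list with components `perm` (charge-charge), `induction`,
#'   `ext` (the -mu.E_ext part, also contained in `induction`), `se_corr`,
#'   and `total` (all Ha)
#' @export
mm_internal_energy <- function(sites, dipoles, external_field = NULL,
                               cell = NULL, thole_a = 0.39) {
  pd <- .mm_pair_data(sites, cell)
  n <- pd$n
  if (is.null(external_field)) external_field <- matrix(0, n, 3)
  external_field <- matrix(external_field, n, 3)
  mu <- do.call(rbind, lapply(dipoles, `[[`, "mu"))
  if (is.null(mu)) mu <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    if (pd$alpha[i] == 0 && any(mu[i, ] != 0))
      stop("site ", i, " has alpha = 0 but a nonzero induced dipole")
  }
  # permanent-permanent
  uqq <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i || pd$frag[i] == pd$frag[j]) next
    dr <- .min_image(cell, matrix(pd$pos[i, ] - pd$pos[j, ], 1))
    uqq <- uqq + pd$q[i] * pd$q[j] / sqrt(sum(dr^2))
  }
  E0 <- .permanent_field(pd, cell, thole_a)
  u_ext <- -sum(mu * external_field)
  u_ind <- -sum(mu * E0) + u_ext
  pol <- which(pd$alpha > 0)
  for (i in pol) u_ind <- u_ind + sum(mu[i, ]^2) / (2 * pd$alpha[i])
  for (i in pol) for (j in pol) {
    if (j <= i) next
    dr <- .min_image(cell, matrix(pd$pos[i, ] - pd$pos[j, ], 1))
    r <- sqrt(sum(dr^2))
    lam <- .thole(r, pd$alpha[i], pd$alpha[j], thole_a)
    u_ind <- u_ind - sum(mu[i, ] * .dipole_field_one(dr, r, mu[j, ], lam))
  }
  kse <- vapply(sites, `[[`, numeric(1), "k_SE")
  u_se <- 0
  for (i in seq_len(n)) {
    dm <- mu[i, ] - dipoles[[i]]$mu_ref
    u_se <- u_se + kse[i] * sum(dm^2)
  }
  list(perm = uqq, induction = u_ind, ext = u_ext, se_corr = u_se,
       total = uqq + u_ind + u_se)
}

#' Induced dipoles of the isolated MM subsystem
#'
#' Solves the dipoles with zero external field and stores each result in
#' `mu_ref` as the reference dipole mu' for the self-energy correction.
#'
#' @inheritParams solve_induced_dipoles
#' @return list of `dfq_induced_dipole` with `mu` = `mu_ref` = mu'
#' @export
isolated_mm_reference <- function(sites, cell = NULL, thole_a = 0.39,
                                  tol = 1e-8) {
  d <- solve_induced_dipoles(sites, NULL, cell, thole_a, tol)
  lapply(d, function(x) induced_dipole(x$site_index, x$mu, x$mu))
}
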