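# Shared fixtures and independent oracles used across the suite.
# Everything here is built in code at test time; nothing is read from disk.

# small cubic grid reused by cheap unit tests
tiny_grid <- function(L = 12, cutoff = 25) {
  build_grid(simulation_cell(L), cutoff)
}

# periodic normalized Gaussian density as a field (package internals are
# exercised elsewhere; this wrapper just centralizes construction)
gaussian_density <- function(grid, center, sigma, amount) {
  s <- mm_site(center, "O", q = element_defaults("O")$N - amount,
               sigma_q = sigma)
  charge_density(s, grid)
}

# closed-form Coulomb energy of two spherical Gaussians (open boundary):
# q1 q2 erf(d / sqrt(2 (s1^2 + s2^2))) / d
gauss_pair_energy <- function(q1, s1, q2, s2, d) {
  q1 * q2 * .erf_num(d / sqrt(2 * (s1^2 + s2^2))) / d
}

.erf_num <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# finite-difference functional-derivative check: compares
# (E[rho + eps b] - E[rho - eps b]) / (2 eps) against int v b for a
# localized Gaussian bump b, over a range of eps.  Returns the smallest
# relative error across the eps ladder.
fd_derivative_error <- function(fun, rho, bump_center = NULL,
                                eps_ladder = c(1e-3, 1e-4, 1e-5)) {
  g <- rho$grid
  if (is.null(bump_center)) {
    L <- diag(g$cell$lattice)
    bump_center <- L / 2 + c(0.7, -0.53, 0.41)
  }
  b <- gaussian_density(g, bump_center, 1.0, 0.05)
  res <- fun(rho)
  an <- integrate_field(scalar_field(g, res$potential$values * b$values))
  errs <- vapply(eps_ladder, function(eps) {
    ep <- fun(scalar_field(g, rho$values + eps * b$values))$energy
    em <- fun(scalar_field(g, rho$values - eps * b$values))$energy
    abs((ep - em) / (2 * eps) / an - 1)
  }, numeric(1))
  min(errs)
}

# smooth strictly positive test density: Gaussian blob on a constant
# background (avoids the near-vacuum regime in derivative tests)
smooth_test_density <- function(grid, amount = 2, background = 0.02) {
  L <- diag(grid$cell$lattice)
  rho <- gaussian_density(grid, L / 2, 1.2, amount)
  scalar_field(grid, rho$values + background)
}

# independent ground-state eigensolver: split-operator imaginary-time
# propagation for one particle in -0.5 lap + v, on the same grid
imaginary_time_ground_state <- function(v_ext, tau = 0.05, max_steps = 6000,
                                        tol = 1e-12) {
  g <- v_ext$grid
  L <- diag(g$cell$lattice)
  psi <- exp(-(distance_field(g, L / 2)$values)^2)
  ekin_half <- exp(-0.25 * tau * g$g2)
  vfac <- exp(-tau * v_ext$values)
  lap <- function(x) Re(stats::fft(-g$g2 * stats::fft(x),
                                   inverse = TRUE)) / length(x)
  energy <- function(psi) {
    h <- -0.5 * lap(psi) + v_ext$values * psi
    sum(psi * h) * g$voxel
  }
  E_old <- Inf
  for (i in seq_len(max_steps)) {
    ph <- stats::fft(psi) * ekin_half
    psi <- Re(stats::fft(ph, inverse = TRUE)) / length(psi) * vfac
    ph <- stats::fft(psi) * ekin_half
    psi <- Re(stats::fft(ph, inverse = TRUE)) / length(psi)
    psi <- psi / sqrt(sum(psi^2) * g$voxel)
    if (i %% 200 == 0) {
      E <- energy(psi)
      if (abs(E - E_old) < tol) break
      E_old <- E
    }
  }
  energy(psi)
}

# dense direct solution of the coupled induced-dipole equations:
# (A^-1 - T) mu = E0 solved as one 3n x 3n linear system, undamped
# tensors unless a Thole factor is supplied
dense_dipole_solution <- function(sites, external_field = NULL, cell = NULL,
                                  thole_a = 0.39) {
  n <- length(sites)
  pos <- do.call(rbind, lapply(sites, `[[`, "position"))
  alpha <- vapply(sites, `[[`, numeric(1), "alpha")
  q <- vapply(sites, `[[`, numeric(1), "q")
  frag <- vapply(seq_len(n), function(i) {
    f <- sites[[i]]$fragment
    if (is.null(f) || is.na(f)) -i else as.numeric(f)
  }, numeric(1))
  if (is.null(external_field)) external_field <- matrix(0, n, 3)
  external_field <- matrix(external_field, n, 3)
  mi <- function(v) {
    if (is.null(cell)) return(v)
    f <- v %*% cell$inv_lattice
    (f - round(f)) %*% cell$lattice
  }
  thole <- function(r, ai, aj) {
    if (!is.finite(thole_a) || ai <= 0 || aj <= 0) return(c(1, 1))
    u <- r / (ai * aj)^(1 / 6); au3 <- thole_a * u^3; e <- exp(-au3)
    c(1 - e, 1 - (1 + au3) * e)
  }
  pol <- which(alpha > 0)
  m <- length(pol)
  if (m == 0) return(matrix(0, n, 3))
  E0 <- external_field
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || frag[i] == frag[j]) next
    dr <- as.numeric(mi(matrix(pos[i, ] - pos[j, ], 1)))
    r <- sqrt(sum(dr^2))
    lam <- thole(r, alpha[i], alpha[j])
    E0[i, ] <- E0[i, ] + lam[1] * q[j] * dr / r^3
  }
  A <- matrix(0, 3 * m, 3 * m)
  b <- numeric(3 * m)
  for (a in seq_len(m)) {
    i <- pol[a]
    A[(3 * a - 2):(3 * a), (3 * a - 2):(3 * a)] <- diag(3) / alpha[i]
    b[(3 * a - 2):(3 * a)] <- E0[i, ]
    for (c0 in seq_len(m)) {
      if (c0 == a) next
      j <- pol[c0]
      dr <- as.numeric(mi(matrix(pos[i, ] - pos[j, ], 1)))
      r <- sqrt(sum(dr^2))
      lam <- thole(r, alpha[i], alpha[j])
      Tij <- (3 * lam[2] * outer(dr, dr) / r^2 - lam[1] * diag(3)) / r^3
      A[(3 * a - 2):(3 * a), (3 * c0 - 2):(3 * c0)] <- -Tij
    }
  }
  mu <- matrix(0, n, 3)
  sol <- solve(A, b)
  for (a in seq_len(m)) mu[pol[a], ] <- sol[(3 * a - 2):(3 * a)]
  mu
}
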