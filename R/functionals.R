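#' @title Orbital-free density functionals
#' @description Semilocal kinetic-energy and exchange-correlation functionals
#'   evaluated on a periodic grid, each returning the energy and the
#'   functional derivative (potential) delta E / delta rho.
#' @name functionals
NULL

C_TF <- 0.3 * (3 * pi^2)^(2 / 3)          # Thomas-Fermi constant
.C_X <- -0.75 * (3 / pi)^(1 / 3)          # LDA exchange constant

# nonnegative density with a guard against FFT ringing: small negative
# excursions are clamped, genuinely negative densities are rejected
.clamp_density <- function(rho, what = "density") {
  mx <- max(rho, 0)
  if (min(rho) < -0.05 * max(mx, 1e-8))
    stop("negative ", what, " values (min ", format(min(rho)), ")")
  pmax(rho, 0)
}

#' Kinetic-functional configuration
#'
#' @param family one of "TF", "vW", "TFvW" (TF + lambda * vW) or "GGA"
#' @param lambda von Weizsacker fraction for the TFvW family (0..1)
#' @param mu_k,kappa_k GGA enhancement-factor parameters
#'   F(s) = 1 + mu_k s^2 / (1 + mu_k s^2 / kappa_k).  Defaults are the
#'   revAPBEk values (mu from the APBE exchange-derived gradient expansion,
#'   kappa revised for kinetic energies).
#' @return object of class `dfq_kinetic_config`
#' @export
kinetic_config <- function(family = c("GGA", "TF", "vW", "TFvW"),
                           lambda = 1, mu_k = 0.23889, kappa_k = 1.245) {
  family <- match.arg(family)
  stopifnot(lambda >= 0, lambda <= 1, kappa_k > 0, mu_k >= 0)
  structure(list(family = family, lambda = lambda,
                 mu_k = mu_k, kappa_k = kappa_k),
            class = "dfq_kinetic_config")
}

#' Functional evaluation result
#' @param energy energy in Hartree
#' @param potential `dfq_field` with delta E / delta rho (Ha per electron)
#' @return object of class `dfq_functional_result`
#' @export
functional_result <- function(energy, potential) {
  stopifnot(is.finite(energy), inherits(potential, "dfq_field"))
  structure(list(energy = energy, potential = potential),
            class = "dfq_functional_result")
}

#' Thomas-Fermi kinetic energy
#'
#' E = C_TF int rho^(5/3), v = (5/3) C_TF rho^(2/3).
#'
#' @param rho `dfq_field`, nonnegative electron density
#' @return `dfq_functional_result`
#' @export
thomas_fermi <- function(rho) {
  g <- rho$grid
  r <- .clamp_density(rho$values)
  r53 <- r^(5 / 3)
  functional_result(C_TF * sum(r53) * g$voxel,
                    scalar_field(g, (5 / 3) * C_TF * r^(2 / 3)))
}

#' von Weizsacker kinetic energy
#'
#' E = int |grad rho|^2 / (8 rho), exact for a single (doubly occupied or
#' bosonic) orbital.  The density is floored at 1e-12 e/bohr^3 inside
#' quotients to regularize empty regions.
#'
#' @param rho `dfq_field`, nonnegative electron density
#' @return `dfq_functional_result`
#' @export
von_weizsacker <- function(rho) {
  g <- rho$grid
  r <- pmax(.clamp_density(rho$values), 1e-12)
  gr <- .grad_arrays(g, rho$values)
  g2 <- gr[[1]]^2 + gr[[2]]^2 + gr[[3]]^2
  e <- sum(g2 / (8 * r)) * g$voxel
  lap <- .lap_array(g, rho$values)
  v <- g2 / (8 * r^2) - lap / (4 * r)
  functional_result(e, scalar_field(g, v))
}

# shared machinery for GGA functionals of the form
#   e(rho, |grad rho|^2) = c * rho^p * F(s^2),
#   s^2 = |grad rho|^2 / (4 (3 pi^2)^(2/3) rho^(8/3))
# F_fun(p2) returns list(F, dF) with dF = dF/d(s^2).
.gga_eval <- function(rho, c0, pw, F_fun, floor_rho = 1e-12) {
  g <- rho$grid
  r <- pmax(.clamp_density(rho$values), floor_rho)
  gr <- .grad_arrays(g, rho$values)
  sig <- gr[[1]]^2 + gr[[2]]^2 + gr[[3]]^2
  k2 <- 4 * (3 * pi^2)^(2 / 3)
  s2 <- sig / (k2 * r^(8 / 3))
  Ff <- F_fun(s2)
  rp <- r^pw
  e <- c0 * sum(rp * Ff$F) * g$voxel
  # v = de/drho - 2 div( de/dsigma grad rho )
  dp_drho <- -(8 / 3) * s2 / r
  de_drho <- c0 * (pw * r^(pw - 1) * Ff$F + rp * Ff$dF * dp_drho)
  de_dsig <- c0 * rp * Ff$dF / (k2 * r^(8 / 3))
  hx <- 2 * de_dsig * gr[[1]]; hy <- 2 * de_dsig * gr[[2]]
  hz <- 2 * de_dsig * gr[[3]]
  v <- de_drho - .div_arrays(g, hx, hy, hz)
  functional_result(e, scalar_field(g, v))
}

#' GGA kinetic energy with a Pade enhancement factor
#'
#' E = C_TF int rho^(5/3) F(s), F(s) = 1 + mu s^2 / (1 + mu s^2 / kappa),
#' s = |grad rho| / (2 (3 pi^2)^(1/3) rho^(4/3)).  With the default
#' (mu, kappa) this is the revAPBEk enhancement form.  With mu = 0 the
#' energy reduces bit-for-bit to Thomas-Fermi.
#'
#' @param rho `dfq_field`, nonnegative electron density
#' @param cfg `dfq_kinetic_config` with family "GGA"
#' @return `dfq_functional_result`
#' @export
gga_kinetic <- function(rho, cfg = kinetic_config("GGA")) {
  stopifnot(inherits(cfg, "dfq_kinetic_config"))
  mu <- cfg$mu_k; ka <- cfg$kappa_k
  .gga_eval(rho, C_TF, 5 / 3, function(p) {
    den <- 1 + mu * p / ka
    list(F = 1 + mu * p / den, dF = mu / den^2)
  })
}

# PW92 correlation energy per electron (spin-unpolarized) as a function of rs
.pw92_ec <- function(rs) {
  A <- 0.031091; a1 <- 0.21370
  b1 <- 7.5957; b2 <- 3.5876; b3 <- 1.6382; b4 <- 0.49294
  srs <- sqrt(rs)
  Q <- 2 * A * (b1 * srs + b2 * rs + b3 * rs * srs + b4 * rs^2)
  -2 * A * (1 + a1 * rs) * log1p(1 / Q)
}

# PBE correlation energy density e_c(rho, sigma) [Ha/bohr^3], vectorized.
.pbe_ec_density <- function(r, sig) {
  gamma_c <- (1 - log(2)) / pi^2
  beta_c <- 0.06672455060314922
  rs <- (3 / (4 * pi * r))^(1 / 3)
  ec <- .pw92_ec(rs)
  kf <- (3 * pi^2 * r)^(1 / 3)
  ks <- sqrt(4 * kf / pi)
  t2 <- sig / (4 * ks^2 * r^2)
  w <- expm1(-ec / gamma_c)
  A <- (beta_c / gamma_c) / pmax(w, 1e-300)
  At2 <- A * t2
  H <- gamma_c * log1p((beta_c / gamma_c) * t2 * (1 + At2) /
                         (1 + At2 + At2^2))
  r * (ec + H)
}

# PBE exchange enhancement
.pbe_fx <- function(p) {
  mu <- 0.2195149727645171; ka <- 0.804
  den <- 1 + mu * p / ka
  list(F = 1 + ka - ka / den, dF = mu / den^2)
}

#' PBE exchange-correlation energy and potential (spin-unpolarized)
#'
#' Exchange uses the published PBE enhancement factor over LDA exchange with
#' an analytic functional derivative; correlation uses the PW92 local part
#' plus the PBE gradient correction H(t), with the pointwise derivatives
#' d e_c / d rho and d e_c / d |grad rho|^2 evaluated by high-order-accurate
#' centered differences of the closed-form energy density (the energy itself
#' is fully analytic).
#'
#' @param rho `dfq_field`, nonnegative electron density
#' @return `dfq_functional_result`
#' @export
xc_energy <- function(rho) {
  g <- rho$grid
  ex <- .gga_eval(rho, .C_X, 4 / 3, .pbe_fx)
  # correlation
  r <- pmax(.clamp_density(rho$values), 1e-12)
  gr <- .grad_arrays(g, rho$values)
  sig <- gr[[1]]^2 + gr[[2]]^2 + gr[[3]]^2
  e_arr <- .pbe_ec_density(r, sig)
  ec <- sum(e_arr) * g$voxel
  hr <- 1e-5 * r
  de_drho <- (.pbe_ec_density(r + hr, sig) - .pbe_ec_density(r - hr, sig)) /
    (2 * hr)
  hs <- 1e-5 * sig + 1e-14
  de_dsig <- (.pbe_ec_density(r, sig + hs) - .pbe_ec_density(r, sig - hs)) /
    (2 * hs)
  hx <- 2 * de_dsig * gr[[1]]; hy <- 2 * de_dsig * gr[[2]]
  hz <- 2 * de_dsig * gr[[3]]
  vc <- de_drho - .div_arrays(g, hx, hy, hz)
  functional_result(ex$energy + ec,
                    scalar_field(g, ex$potential$values + vc))
}

# Combined semilocal evaluation sharing FFTs: for one density, optionally a
# GGA/TF kinetic functional and/or PBE xc, returning separate energies but a
# single summed potential array (one spectral divergence for all gradient
# terms).  `kin_scale` multiplies the kinetic contribution (use -1 to
# subtract, e.g. the additive part inside a nonadditive difference).
.sl_combined <- function(grid, rho_vals, kin_cfg = NULL, with_xc = TRUE,
                         kin_scale = 1, rho_hat = NULL,
                         need_potential = TRUE) {
  r <- pmax(.clamp_density(rho_vals), 1e-12)
  if (is.null(rho_hat)) rho_hat <- .fftn(rho_vals)
  dh <- rho_hat * grid$dmask
  gx <- .ifftn_re(1i * grid$gx * dh)
  gy <- .ifftn_re(1i * grid$gy * dh)
  gz <- .ifftn_re(1i * grid$gz * dh)
  sig <- gx^2 + gy^2 + gz^2
  k2 <- 4 * (3 * pi^2)^(2 / 3)
  r83 <- r^(8 / 3)
  s2 <- sig / (k2 * r83)
  e_kin <- 0; e_xc <- 0
  de_drho <- array(0, dim = grid$shape)
  de_dsig <- array(0, dim = grid$shape)
  if (!is.null(kin_cfg)) {
    if (kin_cfg$family == "TF") {
      e_kin <- C_TF * sum(r^(5 / 3)) * grid$voxel
      de_drho <- de_drho + kin_scale * (5 / 3) * C_TF * r^(2 / 3)
    } else if (kin_cfg$family == "GGA") {
      mu <- kin_cfg$mu_k; ka <- kin_cfg$kappa_k
      den <- 1 + mu * s2 / ka
      Fk <- 1 + mu * s2 / den
      dFk <- mu / den^2
      r53 <- r^(5 / 3)
      e_kin <- C_TF * sum(r53 * Fk) * grid$voxel
      de_drho <- de_drho + kin_scale * C_TF *
        ((5 / 3) * r^(2 / 3) * Fk - r53 * dFk * (8 / 3) * s2 / r)
      de_dsig <- de_dsig + kin_scale * C_TF * r53 * dFk / (k2 * r83)
    } else stop("combined evaluator supports TF or GGA kinetic families")
    e_kin <- e_kin * kin_scale
  }
  if (with_xc) {
    fx <- .pbe_fx(s2)
    r43 <- r^(4 / 3)
    e_x <- .C_X * sum(r43 * fx$F) * grid$voxel
    de_drho <- de_drho + .C_X *
      ((4 / 3) * r^(1 / 3) * fx$F - r43 * fx$dF * (8 / 3) * s2 / r)
    de_dsig <- de_dsig + .C_X * r43 * fx$dF / (k2 * r83)
    e_arr <- .pbe_ec_density(r, sig)
    e_c <- sum(e_arr) * grid$voxel
    hr <- 1e-5 * r
    de_drho <- de_drho +
      (.pbe_ec_density(r + hr, sig) - .pbe_ec_density(r - hr, sig)) / (2 * hr)
    hs <- 1e-5 * sig + 1e-14
    de_dsig <- de_dsig +
      (.pbe_ec_density(r, sig + hs) - .pbe_ec_density(r, sig - hs)) / (2 * hs)
    e_xc <- e_x + e_c
  }
  v <- if (need_potential)
    de_drho - .div_arrays(grid, 2 * de_dsig * gx, 2 * de_dsig * gy,
                          2 * de_dsig * gz) else NULL
  list(e_kin = e_kin, e_xc = e_xc, v = v, rho_hat = rho_hat)
}

#' Evaluate a kinetic functional chosen by configuration
#'
#' @param rho `dfq_field`
#' @param cfg `dfq_kinetic_config`
#' @return `dfq_functional_result`
#' @export
kinetic_energy <- function(rho, cfg) {
  stopifnot(inherits(cfg, "dfq_kinetic_config"))
  switch(cfg$family,
    TF = thomas_fermi(rho),
    vW = von_weizsacker(rho),
    TFvW = {
      tf <- thomas_fermi(rho); vw <- von_weizsacker(rho)
      functional_result(tf$energy + cfg$lambda * vw$energy,
                        scalar_field(rho$grid,
                                     tf$potential$values +
                                       cfg$lambda * vw$potential$values))
    },
    GGA = gga_kinetic(rho, cfg))
}
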