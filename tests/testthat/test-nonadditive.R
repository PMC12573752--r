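# fields for a small two-fragment configuration, built once
local_nad_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    g <- tiny_grid(L = 14, cutoff = 20)
    geo <- generate_dimer_scan(3.0, 3.0, 1, cell_edge = bohr_to_ang(14))[[1]]
    sitesA <- geometry_to_sites(geo, role = NULL)[1:3]
    sitesB <- geometry_to_sites(geo, role = NULL)[4:6]
    rhoA <- assemble_mm_density(sitesA, list(), g)
    rhoB <- assemble_mm_density(sitesB, list(), g)
    vA <- mm_ionic_potential(sitesA, g)
    vB <- mm_ionic_potential(sitesB, g)
    cache <<- list(g = g, rhoA = rhoA, rhoB = rhoB, vA = vA, vB = vB)
    cache
  }
})

test_that("nonadditive energy vanishes for an empty partner and is symmetric", {
  fx <- local_nad_fixture()
  z <- scalar_field(fx$g, 0)
  nb <- nonadditive_energy(fx$rhoA, z, fx$vA, z)
  expect_equal(nb$T_s_nad, 0, tolerance = 1e-10)
  expect_equal(nb$E_xc_nad, 0, tolerance = 1e-10)
  expect_equal(nb$E_coul_cross, 0, tolerance = 1e-12)
  expect_equal(nb$total_nad, 0, tolerance = 1e-10)

  ab <- nonadditive_energy(fx$rhoA, fx$rhoB, fx$vA, fx$vB)
  ba <- nonadditive_energy(fx$rhoB, fx$rhoA, fx$vB, fx$vA)
  expect_equal(ab$total_nad, ba$total_nad, tolerance = 1e-12)
  expect_equal(ab$T_s_nad, ba$T_s_nad, tolerance = 1e-12)
  expect_equal(ab$E_xc_nad, ba$E_xc_nad, tolerance = 1e-12)
  # breakdown sums to the total
  expect_equal(ab$total_nad,
               ab$T_s_nad + ab$E_xc_nad + ab$E_coul_cross +
                 ab$E_ext_cross_AonB + ab$E_ext_cross_BonA)

  expect_error(nonadditive_energy(fx$rhoA,
                                  scalar_field(tiny_grid(10, 20), 0),
                                  fx$vA, fx$vB), "different grids")
})

test_that("distant neutral fragments: nonadditive energy is purely multipolar", {
  # two water monomers 13 bohr apart (equal to their image separation in a
  # 26 bohr cell): the kinetic/xc overlap terms vanish exponentially and
  # the surviving electrostatics depends only on the multipole moments, so
  # it must be independent of the Gaussian widths used to smear them
  g <- build_grid(simulation_cell(26), 18)
  make_frag <- function(x0, model) {
    geo <- generate_dimer_scan(3.0, 3.0, 1, cell_edge = bohr_to_ang(26))[[1]]
    keep <- geo$fragment == 1
    mono <- geometry(geo$elements[keep], geo$positions[keep, ], geo$cell,
                     rep(1L, 3), rep("MM", 3))
    mono$positions <- sweep(mono$positions, 2,
                            c(x0, 13, 13) - mono$positions[1, ], `+`)
    sites <- geometry_to_sites(mono, model, role = "MM")
    # pin the core smearing so both width sets share identical, fully
    # resolved ionic parts; only the electron-density widths vary
    lapply(sites, function(s) {
      s$sigma_core <- if (s$element == "O") 0.7 else 0.6
      s
    })
  }
  ion_cross <- function(sitesA, sitesB) {
    rc <- function(ss) dfqmmm:::.ionic_charge_density(
      lapply(ss, `[[`, "position"),
      vapply(ss, `[[`, numeric(1), "N"),
      vapply(ss, `[[`, numeric(1), "sigma_core"), g)
    integrate_field(scalar_field(g, rc(sitesA)$values *
                                   solve_hartree(rc(sitesB))$values))
  }
  elst <- function(model) {
    sitesA <- make_frag(6.5, model)
    sitesB <- make_frag(19.5, model)
    rhoA <- assemble_mm_density(sitesA, list(), g)
    rhoB <- assemble_mm_density(sitesB, list(), g)
    vA <- mm_ionic_potential(sitesA, g)
    vB <- mm_ionic_potential(sitesB, g)
    nb <- nonadditive_energy(rhoA, rhoB, vA, vB)
    expect_lt(abs(nb$T_s_nad), 2e-5)
    expect_lt(abs(nb$E_xc_nad), 2e-5)
    # the full fragment-fragment electrostatics needs the core-core term,
    # which by definition is not part of the nonadditive energy; the
    # width-comparison below is on electrostatics only, since the tiny
    # residual kinetic/xc overlap is itself width-dependent
    nb$E_coul_cross + nb$E_ext_cross_AonB + nb$E_ext_cross_BonA +
      ion_cross(sitesA, sitesB)
  }
  e_narrow <- elst(mm_model(sigma_q = c(O = 1.0, H = 0.85),
                            sigma_mu = c(O = 1.0, H = 0.85)))
  e_wide <- elst(mm_model(sigma_q = c(O = 1.5, H = 1.3),
                          sigma_mu = c(O = 1.6, H = 1.4)))
  expect_lt(abs(e_narrow - e_wide), 2e-6)
  # and the interaction itself is of dipole-dipole magnitude
  expect_lt(abs(e_narrow), 1e-3)
})

test_that("T_s_nad decays monotonically to zero beyond overlap range", {
  g <- build_grid(simulation_cell(24), 16)
  s0 <- mm_site(c(6, 12, 12), "O", q = -0.8)
  rhoA <- charge_density(s0, g)
  seps <- c(4, 6, 8, 10)
  ts <- vapply(seps, function(d) {
    sB <- mm_site(c(6 + d, 12, 12), "O", q = -0.8)
    rhoB <- charge_density(sB, g)
    z <- scalar_field(g, 0)
    nonadditive_energy(rhoA, rhoB, z, z)$T_s_nad
  }, numeric(1))
  expect_true(all(diff(abs(ts)) < 0))
  expect_lt(abs(ts[length(ts)]), 1e-5)
})

test_that("embedding potential is the functional derivative of the nonadditive energy", {
  fx <- local_nad_fixture()
  g <- fx$g
  v_emb <- embedding_potential_qm(fx$rhoA, fx$rhoB, fx$vB)
  bump <- gaussian_density(g, c(7.3, 6.5, 7.1), 1.0, 0.05)
  an <- integrate_field(scalar_field(g, v_emb$values * bump$values))
  errs <- vapply(c(1e-3, 1e-4), function(eps) {
    ep <- nonadditive_energy(scalar_field(g, fx$rhoA$values + eps * bump$values),
                             fx$rhoB, fx$vA, fx$vB)$total_nad
    em <- nonadditive_energy(scalar_field(g, fx$rhoA$values - eps * bump$values),
                             fx$rhoB, fx$vA, fx$vB)$total_nad
    abs((ep - em) / (2 * eps) / an - 1)
  }, numeric(1))
  expect_lt(min(errs), 1e-4)

  # empty environment: identically zero potential
  z <- scalar_field(g, 0)
  v0 <- embedding_potential_qm(fx$rhoA, z, z)
  expect_lt(max(abs(v0$values)), 1e-10)
})

test_that("embedding potential of a neutral MM fragment has no monopole tail", {
  g <- build_grid(simulation_cell(24), 16)
  geo <- generate_dimer_scan(3.0, 3.0, 1, cell_edge = bohr_to_ang(24))[[1]]
  sites <- geometry_to_sites(geo, role = NULL)[1:3]
  rhoMM <- assemble_mm_density(sites, list(), g)
  vMM <- mm_ionic_potential(sites, g)
  rhoQM <- scalar_field(g, 0)
  v_emb <- embedding_potential_qm(rhoQM, rhoMM, vMM)
  ctr <- sites[[1]]$position
  dfld <- distance_field(g, ctr)
  v_at <- function(r) {
    m <- abs(dfld$values - r) < 0.3
    mean(v_emb$values[m])
  }
  # no monopole: the shell-averaged potential difference is far below what
  # a unit monopole tail would give (the residual is higher-multipole)
  dv <- abs(v_at(6) - v_at(9))
  monopole_dv <- abs(1 / 6 - 1 / 9)
  expect_lt(dv / monopole_dv, 0.5)
})

test_that("QM field at MM sites: zero, cancellation and Coulomb far field", {
  g <- build_grid(simulation_cell(24), 25)
  z <- scalar_field(g, 0)
  site <- mm_site(c(18, 12, 12), "O", q = -0.8)
  expect_equal(qm_field_at_mm_sites(z, z, list(site)), matrix(0, 1, 3))

  # neutral spherical fragment: ionic charge exactly canceled by an
  # electron density of identical profile -> field below discretization noise
  ctr <- c(8, 12, 12)
  at <- list(positions = list(ctr), elements = "O", N = 6,
             sigma_core = 0.7, n_electrons = 6)
  v_ion <- qm_ionic_potential(at, g)
  rho_e <- gaussian_density(g, ctr, 0.7, 6)
  E <- qm_field_at_mm_sites(rho_e, v_ion, list(site))
  expect_lt(max(abs(E)), 1e-8)

  # net-charge fragment: |E| ~ Q / d^2 radially (with a residual from
  # periodic images at this cell size)
  rho_e2 <- gaussian_density(g, ctr, 0.7, 5)   # net ion charge +1
  d <- sqrt(sum((site$position - ctr)^2))
  E2 <- qm_field_at_mm_sites(rho_e2, v_ion, list(site))
  radial <- (site$position - ctr) / d
  expect_equal(as.numeric(E2 / sqrt(sum(E2^2))), radial, tolerance = 0.05)
  expect_equal(sqrt(sum(E2^2)), 1 / d^2, tolerance = 0.08)
})
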