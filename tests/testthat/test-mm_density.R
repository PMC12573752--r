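test_that("charge density integrates to N - q and is periodic", {
  g <- tiny_grid()
  s <- mm_site(c(6, 6, 6), "O", q = -0.8476)
  rho <- charge_density(s, g)
  expect_equal(integrate_field(rho), 6.8476, tolerance = 1e-6 * 6.8476)
  # translation by a full lattice vector gives the identical field
  s2 <- mm_site(c(6 + 12, 6, 6 - 12), "O", q = -0.8476)
  expect_equal(charge_density(s2, g)$values, rho$values, tolerance = 1e-12)
  # under-resolved width is rejected
  expect_error(charge_density(mm_site(c(6, 6, 6), "O", q = 0,
                                      sigma_q = 0.1), g), "under-resolved")
})

test_that("dipole density integrates to zero with first moment = mu", {
  g <- tiny_grid()
  s <- mm_site(c(6.2, 5.9, 6.1), "O", q = -0.8)
  mu <- c(0.12, -0.07, 0.21)
  rho <- dipole_density(induced_dipole(1, mu), s, g)
  expect_lt(abs(integrate_field(rho)), 1e-8)
  expect_equal(dipole_density(induced_dipole(1, c(0, 0, 0)), s, g)$values,
               array(0, dim = g$shape))
  # numeric first-moment quadrature with minimum-image displacements
  fr <- dfqmmm:::.frac_coords(g$cell, s$position)
  sh <- g$shape
  wrap <- function(x) x - round(x)
  f1 <- wrap((seq_len(sh[1]) - 1) / sh[1] - fr[1])
  f2 <- wrap((seq_len(sh[2]) - 1) / sh[2] - fr[2])
  f3 <- wrap((seq_len(sh[3]) - 1) / sh[3] - fr[3])
  A <- g$cell$lattice
  ax_arr <- dfqmmm:::.axis_array
  dx <- ax_arr(f1 * A[1, 1], sh, 1) + ax_arr(f2 * A[2, 1], sh, 2) +
    ax_arr(f3 * A[3, 1], sh, 3)
  dy <- ax_arr(f1 * A[1, 2], sh, 1) + ax_arr(f2 * A[2, 2], sh, 2) +
    ax_arr(f3 * A[3, 2], sh, 3)
  dz <- ax_arr(f1 * A[1, 3], sh, 1) + ax_arr(f2 * A[2, 3], sh, 2) +
    ax_arr(f3 * A[3, 3], sh, 3)
  m <- c(sum(dx * rho$values), sum(dy * rho$values),
         sum(dz * rho$values)) * g$voxel
  expect_equal(m, mu, tolerance = 1e-3)
  # second moments vanish by symmetry (odd function times Gaussian)
  quad <- c(sum(dx^2 * rho$values), sum(dy^2 * rho$values),
            sum(dz^2 * rho$values)) * g$voxel
  expect_lt(max(abs(quad)), 1e-6)
})

test_that("assembled MM density is additive, permutation invariant and charge-correct", {
  g <- tiny_grid()
  geo <- generate_dimer_scan(3.2, 3.2, 1, cell_edge = bohr_to_ang(12))[[1]]
  sites <- geometry_to_sites(geo, role = NULL)
  dip <- lapply(seq_along(sites), function(i)
    induced_dipole(i, mu = 0.05 * c(sin(i), cos(i), 0.3 * i)))
  rho <- assemble_mm_density(sites, dip, g)
  Nq <- sum(vapply(sites, function(s) s$N - s$q, numeric(1)))
  expect_equal(integrate_field(rho), Nq, tolerance = 1e-8)
  # one site, no dipoles = its charge density
  expect_equal(assemble_mm_density(sites[1], list(), g)$values,
               charge_density(sites[[1]], g)$values, tolerance = 1e-14)
  # additivity over disjoint site lists
  rhoA <- assemble_mm_density(sites[1:3], dip[1:3], g)
  dipB <- lapply(4:6, function(i) induced_dipole(i - 3L, dip[[i]]$mu))
  rhoB <- assemble_mm_density(sites[4:6], dipB, g)
  expect_equal(rho$values, rhoA$values + rhoB$values, tolerance = 1e-12)
  # permutation invariance
  perm <- c(3, 1, 2, 6, 5, 4)
  dipP <- lapply(seq_along(perm), function(k)
    induced_dipole(k, dip[[perm[k]]]$mu))
  rhoP <- assemble_mm_density(sites[perm], dipP, g)
  expect_equal(rhoP$values, rho$values, tolerance = 1e-12)
  # dangling dipole reference
  expect_error(assemble_mm_density(sites[1:2],
                                   list(induced_dipole(5, c(0.1, 0, 0))), g),
               "site 5")
})

test_that("MM ionic potential has the -N/r far field and superposes", {
  cell <- simulation_cell(40)
  g <- build_grid(cell, 12)
  s <- mm_site(c(20, 20, 20), "O", q = -0.8, sigma_core = 0.7)
  v <- mm_ionic_potential(list(s), g)
  dfld <- distance_field(g, s$position)
  # compare potential differences (the G = 0 convention leaves an additive
  # constant): v(r1) - v(r2) vs -N/r1 + N/r2 at r = 6 sigma_core and 2x that
  r1 <- 6 * s$sigma_core; r2 <- 12 * s$sigma_core
  m1 <- abs(dfld$values - r1) < 0.2
  m2 <- abs(dfld$values - r2) < 0.2
  got <- mean(v$values[m1]) - mean(v$values[m2])
  # the neutralizing background adds a quadratic term 2 pi N r^2 / (3 V)
  want <- -s$N / r1 + s$N / r2 + 2 * pi * s$N * (r1^2 - r2^2) / (3 * 40^3)
  expect_lt(abs(got / want - 1), 0.01)
  expect_equal(mm_ionic_potential(list(), g)$values, array(0, dim = g$shape))
  # superposition
  s2 <- mm_site(c(26, 20, 20), "H", q = 0.4, sigma_core = 0.6)
  v12 <- mm_ionic_potential(list(s, s2), g)
  expect_equal(v12$values,
               v$values + mm_ionic_potential(list(s2), g)$values,
               tolerance = 1e-12)
})

test_that("neutral water MM charge distribution has no monopole", {
  g <- tiny_grid()
  geo <- generate_dimer_scan(3.0, 3.0, 1, cell_edge = bohr_to_ang(12))[[1]]
  sites <- geometry_to_sites(geo, role = NULL)
  rho_e <- assemble_mm_density(sites, list(), g)
  # total charge: +N cores minus electrons = sum q = 0 for neutral water
  expect_equal(integrate_field(rho_e),
               sum(vapply(sites, `[[`, numeric(1), "N")),
               tolerance = 1e-8)
  expect_equal(sum(vapply(sites, `[[`, numeric(1), "q")), 0,
               tolerance = 1e-12)
})

test_that("cube export preserves the field integral and shape header", {
  g <- build_grid(simulation_cell(8), 10)
  rho <- gaussian_density(g, c(4, 4, 4), 1.2, 2)
  geo <- geometry("O", matrix(c(4, 4, 4), 1), cell = g$cell)
  path <- tempfile(fileext = ".cube")
  write_cube(rho, geo, path)
  lines <- readLines(path)
  hdr <- as.numeric(strsplit(trimws(lines[3]), "\\s+")[[1]])
  expect_equal(hdr[1], 1)   # one atom
  ns <- vapply(4:6, function(i)
    as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]][1]), numeric(1))
  expect_equal(ns, as.numeric(g$shape))
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:7)]), "\\s+")))
  expect_equal(length(vals), prod(g$shape))
  expect_equal(sum(vals) * g$voxel, integrate_field(rho), tolerance = 1e-5)
})
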