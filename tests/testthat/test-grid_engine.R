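test_that("grid construction respects the cutoff-implied spacing bound", {
  # 12.42 A cubic cell at 100 Ha: spacing must stay at or below ~0.23 bohr
  cell <- simulation_cell(ang_to_bohr(12.42))
  g <- build_grid(cell, 100)
  expect_true(all(g$spacing <= pi / sqrt(2 * 100)))
  expect_true(all(g$spacing <= 0.23))

  # h ~ cutoff^(-1/2): quadrupling the cutoff at least halves the bound
  g4 <- build_grid(cell, 400)
  expect_true(all(g4$spacing <= pi / sqrt(2 * 400)))

  # minimum division count before FFT-friendly rounding
  g10 <- build_grid(simulation_cell(10), 100)
  nmin <- ceiling(10 * sqrt(200) / pi)
  expect_true(all(g10$shape >= nmin))
  # shapes are 2,3,5-smooth
  smooth235 <- function(n) {
    for (p in c(2, 3, 5)) while (n %% p == 0) n <- n / p
    n == 1
  }
  expect_true(all(vapply(as.numeric(g10$shape), smooth235, logical(1))))
})

test_that("degenerate cells are rejected", {
  bad <- rbind(c(1, 0, 0), c(2, 0, 0), c(0, 0, 1))
  expect_error(simulation_cell(bad), "linearly independent")
})

test_that("integration is exact for constants and Gaussian normalization", {
  g <- tiny_grid()
  expect_equal(integrate_field(scalar_field(g, 2.5)), 2.5 * 12^3)
  rho <- gaussian_density(g, c(6, 6, 6), 1.1, 3.2)
  expect_equal(integrate_field(rho), 3.2, tolerance = 1e-10)
  # refinement oracle: integral of a smooth field is resolution-independent
  g2 <- build_grid(g$cell, 60)
  rho2 <- gaussian_density(g2, c(6, 6, 6), 1.1, 3.2)
  expect_equal(integrate_field(rho), integrate_field(rho2),
               tolerance = 1e-10)
})

test_that("Hartree solver matches the closed-form two-Gaussian Coulomb energy", {
  cell <- simulation_cell(30)
  g <- build_grid(cell, 30)
  # neutral composite blobs (monopole-free, so periodic images are
  # exponentially suppressed): each is a +1/-1 Gaussian pair of unequal
  # widths; the interaction is a sum of four closed-form pair terms
  blob <- function(pos, sa, sb) {
    a <- gaussian_density(g, pos, sa, 1)
    b <- gaussian_density(g, pos, sb, 1)
    scalar_field(g, a$values - b$values)
  }
  d <- 5
  r1 <- blob(c(15, 15, 15), 1.0, 1.6)
  r2 <- blob(c(15 + d, 15, 15), 1.2, 1.8)
  E12 <- integrate_field(scalar_field(g, r1$values * solve_hartree(r2)$values))
  Eex <- gauss_pair_energy(1, 1.0, 1, 1.2, d) +
    gauss_pair_energy(1, 1.0, -1, 1.8, d) +
    gauss_pair_energy(-1, 1.6, 1, 1.2, d) +
    gauss_pair_energy(-1, 1.6, -1, 1.8, d)
  expect_lt(abs(E12 / Eex - 1), 1e-3)

  # charged single Gaussian: periodic self-energy equals the open-boundary
  # q^2/(2 sqrt(pi) s) plus the cubic Wigner background constant
  # -q^2 2.837297/(2 L) plus the Gaussian-width background term
  # 2 pi q^2 s^2 / V (from the G = 0 removal; independent Ewald oracle)
  s <- 1.0
  r <- gaussian_density(g, c(15, 15, 15), s, 1)
  Eself <- 0.5 * integrate_field(scalar_field(g, r$values *
                                                solve_hartree(r)$values))
  Eexp <- 1 / (2 * sqrt(pi) * s) - 2.837297 / (2 * 30) + 2 * pi * s^2 / 30^3
  expect_lt(abs(Eself - Eexp), 2e-5)

  expect_equal(solve_hartree(scalar_field(g, 0))$values,
               array(0, dim = g$shape))
})

test_that("Hartree interaction energy is translation invariant", {
  g <- tiny_grid()
  pair_E <- function(shift) {
    r1 <- gaussian_density(g, c(4, 6, 6) + shift, 1.0, 1)
    r2 <- gaussian_density(g, c(8, 6, 6) + shift, 1.2, -1)
    rho <- scalar_field(g, r1$values + r2$values)
    0.5 * integrate_field(scalar_field(g, rho$values *
                                         solve_hartree(rho)$values))
  }
  expect_equal(pair_E(c(0, 0, 0)), pair_E(c(1.731, -2.1, 0.44)),
               tolerance = 1e-9)
})

test_that("spectral gradient is exact for plane waves and Gaussians", {
  g <- tiny_grid()
  L <- 12
  x <- (seq_len(g$shape[1]) - 1) * g$spacing[1]
  v <- array(0, g$shape)
  for (i in seq_len(g$shape[1])) v[i, , ] <- sin(2 * pi * x[i] / L)
  gr <- spectral_gradient(scalar_field(g, v))
  expect_equal(gr[[1]]$values[, 1, 1], (2 * pi / L) * cos(2 * pi * x / L),
               tolerance = 1e-12)
  expect_equal(max(abs(gr[[2]]$values)), 0, tolerance = 1e-12)

  expect_equal(spectral_gradient(scalar_field(g, 1.7))[[3]]$values,
               array(0, dim = g$shape))

  # analytic Gaussian gradient (radial component along x through center)
  rho <- gaussian_density(g, c(6, 6, 6), 1.3, 1)
  gx <- spectral_gradient(rho)[[1]]
  i0 <- 1 + round(6 / g$spacing[1])
  xs <- (seq_len(g$shape[1]) - 1) * g$spacing[1] - 6
  gauss <- exp(-xs^2 / (2 * 1.3^2)) / (2 * pi * 1.3^2)^(3 / 2)
  core <- abs(xs) <= 4   # away from the wrap-around tails
  expect_equal(gx$values[core, i0, i0], (-xs / 1.3^2 * gauss)[core],
               tolerance = 1e-6)
})

test_that("divergence of the Hartree gradient reproduces -4 pi rho", {
  g <- tiny_grid()
  rho <- gaussian_density(g, c(6.3, 5.8, 6.1), 1.2, 2)
  rho_mean <- integrate_field(rho) / g$volume
  phi <- solve_hartree(rho)
  gr <- spectral_gradient(phi)
  div <- Reduce(`+`, lapply(1:3, function(a)
    spectral_gradient(gr[[a]])[[a]]$values))
  expect_equal(div, -4 * pi * (rho$values - rho_mean), tolerance = 1e-6)
})

test_that("nearest grid point lookup wraps periodically with deterministic ties", {
  g <- build_grid(simulation_cell(16), 18)  # shape 32, spacing exactly 0.5
  h <- g$spacing[1]
  expect_equal(h, 0.5)
  expect_equal(nearest_grid_index(g, c(0, 0, 0)), c(1L, 1L, 1L))
  expect_equal(nearest_grid_index(g, c(16 - 0.25 * h, 0, 0))[1], 1L)
  expect_equal(nearest_grid_index(g, c(3 * h, 2 * h, h)), c(4L, 3L, 2L))
  # exact (binary-representable) half-way tie falls to the lower index
  expect_equal(nearest_grid_index(g, c(1.25, 0, 0))[1], 3L)
})
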