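test_that("induced dipoles: limits and dense-solver oracle", {
  # alpha = 0 everywhere: all dipoles zero
  g1 <- generate_dimer_scan(3.0, 3.0, 1)[[1]]
  sites0 <- geometry_to_sites(g1, mm_model(alpha_O = 0, alpha_H = 0), role = NULL)
  d0 <- solve_induced_dipoles(sites0, cell = g1$cell)
  expect_true(all(vapply(d0, function(d) all(d$mu == 0), logical(1))))

  # one isolated site in a uniform field: mu = alpha E exactly
  s1 <- mm_site(c(0, 0, 0), "O", q = 0)
  E <- matrix(c(0.013, -0.004, 0.002), 1)
  d1 <- solve_induced_dipoles(list(s1), E, tol = 1e-13)
  expect_equal(d1[[1]]$mu, s1$alpha * as.numeric(E), tolerance = 1e-9)

  # several interacting polarizable sites: match the dense linear solve
  set.seed(11)
  sites <- lapply(1:4, function(i)
    mm_site(c(3 * i + 0.3 * sin(i), 2 * cos(i), 0.5 * i), "O",
            q = 0.1 * (-1)^i))
  Eext <- matrix(stats::rnorm(12, sd = 0.01), 4)
  it <- solve_induced_dipoles(sites, Eext, tol = 1e-12)
  mu_it <- do.call(rbind, lapply(it, `[[`, "mu"))
  mu_dense <- dense_dipole_solution(sites, Eext)
  expect_equal(mu_it, mu_dense, tolerance = 1e-9)

  # water monomer (intramolecular exclusions active) vs dense oracle
  sw <- geometry_to_sites(g1, role = NULL)
  dw <- solve_induced_dipoles(sw, cell = g1$cell, tol = 1e-12)
  mu_w <- do.call(rbind, lapply(dw, `[[`, "mu"))
  expect_equal(mu_w, dense_dipole_solution(sw, cell = g1$cell),
               tolerance = 1e-9)
})

test_that("isolated reference dipoles respect molecular symmetry", {
  # a single water monomer: mu' must lie in the molecular symmetry plane
  # (zero component perpendicular to the HOH plane) for every site
  geo <- generate_dimer_scan(5.0, 5.0, 1)[[1]]
  keep <- geo$fragment == 1
  mono <- geometry(geo$elements[keep], geo$positions[keep, ], geo$cell,
                   geo$fragment[keep], rep("MM", 3))
  sites <- geometry_to_sites(mono, role = "MM")
  mu <- isolated_mm_reference(sites, mono$cell)
  v1 <- mono$positions[2, ] - mono$positions[1, ]
  v2 <- mono$positions[3, ] - mono$positions[1, ]
  nrm <- c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  for (d in mu) expect_lt(abs(sum(d$mu * nrm)), 1e-10)
  expect_equal(mu[[1]]$mu, mu[[1]]$mu_ref)
})

test_that("MM internal energy matches closed forms and a hand-built 2-site case", {
  # single polarizable site, uniform field, no permanent charges, k_SE = 0:
  # total induction energy -alpha E^2 / 2
  s1 <- mm_site(c(0, 0, 0), "O", q = 0)
  E <- matrix(c(0.02, 0, 0), 1)
  d1 <- solve_induced_dipoles(list(s1), E)
  en <- mm_internal_energy(list(s1), d1, E)
  expect_equal(en$total, -0.5 * s1$alpha * 0.02^2, tolerance = 1e-12)

  # correction term vanishes at mu = mu'
  s1$k_SE <- 0.7
  dref <- induced_dipole(1, c(0.1, 0, 0), c(0.1, 0, 0))
  en2 <- mm_internal_energy(list(s1), list(dref), NULL)
  expect_equal(en2$se_corr, 0)
  # ... and contributes k_SE |mu - mu'|^2 otherwise
  dref2 <- induced_dipole(1, c(0.1, 0, 0), c(0.04, 0, 0))
  en3 <- mm_internal_energy(list(s1), list(dref2), NULL)
  expect_equal(en3$se_corr, 0.7 * 0.06^2, tolerance = 1e-14)

  # two-site hand evaluation: charge + polarizable site along z
  qa <- 0.5; r <- 4
  sa <- mm_site(c(0, 0, 0), "H", q = qa, alpha = 0)
  sb <- mm_site(c(0, 0, r), "O", q = -0.2)
  dd <- solve_induced_dipoles(list(sa, sb), tol = 1e-13)
  mu <- dd[[2]]$mu
  # field at b from charge a (Thole damping inactive: alpha_a = 0)
  Eb <- qa * c(0, 0, r) / r^3
  expect_equal(mu, sb$alpha * Eb, tolerance = 1e-10)
  en4 <- mm_internal_energy(list(sa, sb), dd)
  hand <- qa * (-0.2) / r +                          # charge-charge
    (-sum(mu * Eb) + sum(mu^2) / (2 * sb$alpha))     # induction
  expect_equal(en4$total, hand, tolerance = 1e-12)

  # alpha = 0 with nonzero dipole is inconsistent
  expect_error(mm_internal_energy(list(sa, sb),
                                  list(induced_dipole(1, c(0.1, 0, 0)),
                                       induced_dipole(2))),
               "alpha = 0")
})

test_that("converged dipoles minimize the polarization energy functional", {
  geo <- generate_dimer_scan(2.8, 2.8, 1)[[1]]
  sites <- geometry_to_sites(geo, role = NULL)
  dip <- solve_induced_dipoles(sites, cell = geo$cell, tol = 1e-12)
  E0 <- mm_internal_energy(sites, dip, NULL, geo$cell)$total
  for (i in which(vapply(sites, `[[`, numeric(1), "alpha") > 0)) {
    for (ax in 1:3) {
      for (sgn in c(-1, 1)) {
        dp <- dip
        mu <- dp[[i]]$mu; mu[ax] <- mu[ax] + sgn * 1e-3
        dp[[i]] <- induced_dipole(i, mu, dip[[i]]$mu_ref)
        expect_gt(mm_internal_energy(sites, dp, NULL, geo$cell)$total, E0)
      }
    }
  }
})

test_that("MM energy is invariant under global rotation", {
  geo <- generate_dimer_scan(3.1, 3.1, 1)[[1]]
  sites <- geometry_to_sites(geo, role = NULL)
  dip <- solve_induced_dipoles(sites, tol = 1e-12)       # open boundary
  E0 <- mm_internal_energy(sites, dip)$total
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  sitesR <- lapply(sites, function(s) {
    s$position <- as.numeric(R %*% s$position); s
  })
  dipR <- solve_induced_dipoles(sitesR, tol = 1e-12)
  ER <- mm_internal_energy(sitesR, dipR)$total
  expect_equal(ER, E0, tolerance = 1e-10)
  # and the dipoles co-rotate
  for (i in seq_along(dip))
    expect_equal(dipR[[i]]$mu, as.numeric(R %*% dip[[i]]$mu),
                 tolerance = 1e-8)
})

test_that("undamped close polarizable pair triggers the catastrophe detector", {
  alpha <- 9.72
  rcrit <- (4 * alpha^2)^(1 / 6)
  s <- list(mm_site(c(0, 0, 0), "O", q = 0),
            mm_site(c(0, 0, 0.95 * rcrit), "O", q = 0))
  expect_error(solve_induced_dipoles(s, matrix(0.01, 2, 3), thole_a = Inf),
               "polarization catastrophe")
  # with Thole damping on, the same configuration is stable
  expect_no_error(solve_induced_dipoles(s, matrix(0.01, 2, 3)))
})
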