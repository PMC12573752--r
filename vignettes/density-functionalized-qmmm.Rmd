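---
title: "Density-functionalized QM/MM: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-functionalized QM/MM: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Conventional electrostatic-embedding QM/MM couples a quantum region to
classical point charges through bare Coulomb terms.  Two things are lost in
that coupling: Pauli repulsion between the QM electrons and the (implicit)
electrons of the environment, and any quantum-mechanical account of
exchange, correlation and charge penetration across the boundary.  The
consequence is well documented: QM electron density leaks onto the
point charges ("charge spill-out"), and interaction energies depend
strongly on where the QM/MM boundary is drawn.

`dfqmmm` instead treats the MM subsystem as an electronic subsystem.  Every
MM site is assigned a smooth valence electron density,

* permanent charge `q`, valence count `N`:
  `rho_q(r) = (N - q) g_sigma_q(r - R)` with `g` a normalized Gaussian,
* induced point dipole `mu`:
  `rho_mu(r) = -mu . grad g_sigma_mu(r - R)`,

and the atomic cores of both subsystems are represented by analytic local
pseudopotentials `v_loc(r) = -N erf(r / (sqrt(2) sigma_core)) / r`.  The
total density is `rho = rho_QM + rho_MM` and the total energy splits into
additive subsystem terms plus a nonadditive interaction

```
E_nad = T_s^nad + E_xc^nad + Coulomb cross terms + external cross terms,
F^nad[A, B] = F[A + B] - F[A] - F[B],
```

evaluated with orbital-free functionals: a GGA kinetic functional with the
revAPBEk enhancement form (Pade `F(s) = 1 + mu s^2 / (1 + mu s^2 / kappa)`,
`mu = 0.23889`, `kappa = 1.245`, treated as configuration data) and
PBE exchange-correlation.  The nonadditive kinetic term carries the Pauli
repulsion that keeps the QM density out of the MM cores; switching it off
(`include_kinetic = FALSE`) reproduces the spill-out pathology on purpose,
and the test suite measures exactly that.

The functional derivative of `E_nad` with respect to the QM density is the
embedding potential entering the QM Hamiltonian.  It is evaluated in
potential-difference form, `v_F[rho_tot] - v_F[rho_QM]`, which is exact for
any semilocal functional.  In the reverse direction the MM dipoles respond
to the electric field of the QM charge distribution; of the full MM
embedding potential only the classical electrostatic part (ionic plus
Hartree) is kept, because the short-range kinetic/xc terms act where a
point-dipole response model is not meaningful anyway.  The field is sampled
at the grid point nearest each dipole site (ties broken toward the lower
index, deterministically); the QM field is smooth on the scale of one grid
spacing in the MM region, so interpolation buys nothing.

Mutual polarization is reached by an outer loop: assemble `rho_MM` from the
current dipoles, minimize each QM subsystem in its embedding, evaluate the
QM field at the MM sites, re-solve the induced dipoles with damped mixing,
repeat.  Convergence is declared on the total energy (default
`1e-8` Ha/atom) *and* an L2 norm of the QM density change (default `1e-6`),
mirroring the usual practice of calibrating SCF convergence on the density.

## The orbital-free QM engine

The reference formulation drives the QM side with a Kohn-Sham plane-wave
code.  This package substitutes an orbital-free solver so the entire method
runs self-contained: the QM density is parametrized as `rho = phi^2` and
`T_s[rho] = T_TF[rho] + T_vW[phi]` (Thomas-Fermi plus full von Weizsacker)
is minimized together with Hartree, PBE xc, the external potential and the
embedding terms, under the exact electron-count constraint.  The minimizer
is a projected nonlinear conjugate gradient on `phi` with norm-preserving
great-circle steps `phi(theta) = phi cos(theta) + d sin(theta)`; the line
search only ever accepts a decrease, so the energy trace is non-increasing
by construction.  vW is exact for a single orbital, which gives the suite
an independent cross-check: with pure vW and one electron the minimum must
coincide with the lowest eigenvalue of `-1/2 lap + v`, and the tests verify
this against a split-operator imaginary-time eigensolver to 1e-6 Ha.

All QM/MM coupling formulas are engine-agnostic; swapping in an orbital
solver would change none of the embedding machinery.  The price of the
orbital-free engine is quantitative: TF+vW water densities lack shell
structure, so absolute interaction energies are not comparable to
Kohn-Sham benchmarks.  Every quantitative claim the package makes is
therefore a *property* claim (consistency, symmetry, convergence,
derivative exactness), checked against closed forms or independent
numerical oracles, not against published Kohn-Sham numbers.

## Grids, Coulomb and units

Everything lives on one periodic real-space grid shared by QM and MM (the
two-cell plane-wave reduction of the reference implementation is an
optimization, not physics).  The grid is built from an energy cutoff: the
spacing obeys `h <= pi / sqrt(2 E_cut)` per axis and sizes are rounded up
to 2,3,5-smooth integers.  At 100 Ha this bound is 0.222 bohr, consistent
with the conventional "about 0.23 bohr" working resolution; desk-scale
fixtures in the tests use 15-30 Ha, where the smooth Gaussian densities
(widths of about 1 bohr and larger) are fully resolved.

Poisson solves, gradients and Laplacians are spectral.  All Coulomb
objects use the `G = 0`-removed (neutralizing background) convention;
total-charge neutrality is asserted at the driver level, where it holds
for every built-in water system, so background constants cancel in all
reported interaction energies.  Gaussian densities and ionic potentials
are synthesized directly in reciprocal space, which sums periodic images
exactly.  Ion-ion energies are computed on the grid from the smeared cores
with the closed-form Gaussian self-energy `q^2 / (2 sqrt(pi) sigma)`
removed.  Internal units are Hartree atomic units throughout; Angstrom and
kcal/mol appear only in file I/O and reported interaction energies
(1 Ha = 627.509 kcal/mol).

## The built-in polarizable water model

The MM engine is a minimal three-site rigid polarizable model chosen so
that every code path of the embedding (permanent density, dipole density,
mutual polarization, self-energy correction) is exercised by a real force
field rather than a mock:

* rigid gas-phase geometry, r(OH) = 0.9572 A, HOH = 104.52 deg;
* fixed atomic charges q_O = -0.8476 e, q_H = +0.4238 e (the SPC/E set);
* isotropic atomic polarizabilities alpha_O = 8.84, alpha_H = 1.98 bohr^3
  (the TTM4/MB-pol lineage values).  Hydrogens are polarizable on purpose:
  with alpha_H = 0 the dipole-width parameter sigma_mu_H would have no
  effect on any observable and the four-parameter width calibration would
  be singular;
* Thole exponential damping with factor a = 0.39 between polarizable
  sites, 1-2/1-3 intramolecular exclusions for permanent fields;
* dipole self-energy correction `k_SE |mu - mu'|^2` with `mu'` the
  isolated-MM dipoles; `k_SE` defaults to 0 and is exposed as data.

MM-MM interactions use real-space minimum-image Coulomb: at desk scale the
cells are large relative to the clusters, and the density-based grid path
remains available through the same interfaces for anything larger.  The
dipole solver iterates to `max |delta mu| < 1e-8 e bohr` with an a-priori
two-site stability check (`r^6 <= 4 alpha_i alpha_j` with damping
disabled is refused as a polarization catastrophe, naming the pair).

Default Gaussian widths (bohr): sigma_q = 1.2 (O), 1.0 (H); sigma_mu =
1.3 (O), 1.1 (H); sigma_core = sigma_q / 2.  These are starting values of
the calibration, not claims: `fit_widths` adjusts the four widths against
reference interaction energies.  The charge-Gaussian and core widths are
deliberately independent parameters.

## Width calibration and the partition statistic

`width_fit_problem` freezes, per configuration, the isolated QM density
and the induced dipoles under the frozen QM field; the fit objective then
only reassembles `rho_MM(theta)` and re-evaluates the nonadditive terms,
so a bounded L-BFGS-B run over the four widths costs seconds per
configuration instead of full SCF cycles.  The frozen-density
approximation is a calibration device, not part of the physics: production
interaction energies always come from the fully relaxed SCF.  Parameter
recovery on self-generated references (references produced by the model at
known widths, fit started elsewhere) is the identifiability check; the
suite requires recovery within 2%.

For a cluster of `n` molecules split `k` QM / `n - k` MM, all
`choose(n, k)` members of partition `k` would ideally give one interaction
energy.  `partition_rmse` regresses the per-`k` RMSE (about the member
mean) through the origin on `sqrt(choose(n, k))` and converts the slope to
an average error per QM/MM boundary via the half-normal mean-RMS factor:
`error = slope * sqrt(pi / 2)`.  The Monte-Carlo validation in the suite
compares the estimator against the exact finite-sample expectation of a
mean-centered RMSE (a chi_(m-1) moment) rather than the naive asymptotic
value, and checks the `sqrt(pi/2)` factor itself on half-normal draws.
An intercept option exists behind a flag for diagnostic fits.

## Synthetic fixtures: what they emulate, what they do not

The generators stand in for external datasets:

* `generate_dimer_scan`: rigid donor/acceptor water dimers at evenly
  spaced O-O distances (defaults 2.3-7.7 A), with a mirrored-labels
  variant for QM/MM vs MM/QM consistency;
* `generate_symmetric_dimer`: two monomers related by inversion through
  the cell center.  Because the grid is even-sized, inversion maps grid
  points onto grid points, so swapping the QM/MM labels is an *exact*
  symmetry of the discretized model; the suite requires the two labelings
  to agree to 1e-8 Ha.  This is the desk-scale analog of the
  donor/acceptor consistency test, made exact by construction;
* `generate_water_box`: seeded rejection-packed rigid waters (minimum
  O-O 2.4 A) in a 12.42 A cell, 64 molecules by default; ten such boxes
  enumerate the 640 single-molecule interaction tasks of the bulk
  calibration protocol;
* `generate_cluster`: an idealized prism-like hexamer (two stacked
  triangles) with full partition enumeration, and a tetrahedral pentamer
  (first-shell motif).

These are structurally analogous inputs, not reconstructions: random boxes
are not thermalized liquid snapshots, the cluster geometries are idealized
motifs rather than optimized minima, and the orbital-free monomers are not
Kohn-Sham water.  Passing tests therefore demonstrate correctness and
internal consistency of the machinery on realistic topologies, and say
nothing quantitative about real liquid water.  Real geometries flow
through the same `read_xyz` path.

## Numerical choices

* vW regularization: densities floored at 1e-12 e/bohr^3 inside
  quotients; the floor is far below any physical density in the fixtures.
* Functional evaluation clamps negative excursions to zero — FFT ringing
  and, by construction, the negative lobes of dipole densities — and
  rejects densities more negative than 5% of their maximum as a domain
  error.  Deep-MM-core regions where `rho_QM` is
  tiny but `rho_tot` is large are covered by the same floor.
* PBE correlation: energy density is closed-form; its two pointwise
  partial derivatives are taken by centered differences with relative
  step 1e-5, accurate to ~1e-9 — two orders below the 1e-4 bar the
  derivative suite enforces.  Exchange and the kinetic GGA use analytic
  derivatives.
* Spectral derivatives zero the unpaired Nyquist mode on even axes.
* Outer-loop dipole mixing defaults to 0.8.  At desk-scale coupling a
  factor of 0.5 leaves a slow geometric tail (~0.8 per iteration) that
  pushes the dimer fixture past 40 outer iterations; 0.8 converges in
  under 30 with no oscillation.  An oscillation detector aborts with the
  SCF trace when alternating energy steps grow.
* The inner minimizer declares convergence only after two consecutive
  energy changes below threshold; the line search never accepts an
  increase.
* Problem sizes: unit tests run on 24-32^3 grids (10-14 bohr cells,
  15-30 Ha); the paired SCF checks use a 7.5 A cell at 20 Ha (30^3).
  These sizes were chosen as the smallest at which every width satisfies
  the 1.5-spacing resolvability precondition with margin.

## Known limitations

* Orbital-free TF+vW additive kinetic energy: no shell structure, so
  absolute energetics differ from Kohn-Sham; all acceptance checks are
  property-based for this reason.
* Single shared cell and grid; Gamma point only; no open boundaries.
* Charges and dipoles only in the MM density (higher multipoles are
  analytically straightforward but not implemented); atom-centered sites
  only (no off-atom M-sites).
* Rigid monomers, no dispersion correction, no forces, no dynamics.
* The MM-MM Coulomb path is minimum-image real-space; adequate for the
  built-in fixtures, not for genuinely condensed MM phases.
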