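# dfqmmm — density-functionalized QM/MM with orbital-free embedding

`dfqmmm` is an R implementation of QM/MM in which the classical (MM)
subsystem is *density-functionalized*: the force field's permanent point
charges and induced point dipoles are mapped onto smooth Gaussian electron
densities, and the QM–MM interaction is evaluated with orbital-free
nonadditive density functionals instead of bare Coulomb coupling.  The two
subsystems polarize each other to self-consistency.

It is aimed at method developers who want a small, fully inspectable,
self-contained testbed for subsystem-DFT-style embedding: no external
electronic-structure binaries, no pseudopotential files, no force-field
packages — every ingredient, from the FFT Poisson solver to the polarizable
water model, is in this package and covered by oracle-based tests.

## The model

For MM site *i* with permanent charge *q_i* and valence count *N_i*, and
induced dipole **mu**_j:

    rho_MM(r) = sum_i (N_i - q_i) g_sigma(r - R_i)  -  sum_j mu_j . grad g_sigma(r - R_j)

with normalized Gaussians *g* of element-specific widths sigma (the
calibration parameters).  Cores of both subsystems are analytic local
pseudopotentials  v_loc(r) = −N erf(r/(√2 σ_core))/r.  With
rho = rho_QM + rho_MM, the energy is

    E = E[rho_QM] + E_MM + E_nad[rho_QM, rho_MM]
    E_nad = T_s^nad + E_xc^nad + ∫∫ rho_QM rho_MM / |r−r'| + ∫ rho_MM v_QM + ∫ rho_QM v_MM
    F^nad[A,B] = F[A+B] − F[A] − F[B]

where T_s^nad uses a revAPBEk-style GGA kinetic functional (this is the
Pauli repulsion that prevents charge spill-out) and E_xc^nad uses PBE.
δE_nad/δrho_QM is the embedding potential in the QM Hamiltonian; the MM
dipoles respond to the electric field of the QM charge distribution,
sampled at the nearest grid point to each site.  The QM density is obtained
by orbital-free DFT (Thomas–Fermi + von Weizsäcker, rho = phi², projected
conjugate gradient with norm-preserving steps) on a periodic real-space
grid built from an energy cutoff.

## Worked example

A hydrogen-bonded water dimer, donor treated quantum mechanically, acceptor
as polarizable MM:

```r
library(dfqmmm)

geo <- generate_dimer_scan(2.9, 2.9, n_points = 1, cell_edge = 7.5)[[1]]
sys <- qmmm_system(geo, cutoff = 20)      # 20 Ha grid cutoff
res <- run_qmmm(sys)
res
#> dfq_qmmm_result: E = -9.92040485 Ha (converged, 35 outer iterations)

iso <- run_qmmm(qmmm_system(local({      # the QM monomer alone
  keep <- geo$fragment == 1
  geometry(geo$elements[keep], geo$positions[keep, ], geo$cell,
           rep(1L, 3), rep("QM", 3))
}), cutoff = 20), grid = res$grid)

interaction_energy(res, iso, isolated_mm_energy(sys))
#> [1] -15.32439
```

The result object carries the converged QM density (`res$qm[[1]]$density`,
exportable with `write_cube`), the induced dipoles (`res$dipoles`), a full
energy breakdown (`res$breakdown`, printable via `energy_report`) and the
per-iteration SCF trace.  The interaction energy is in kcal/mol; its
magnitude reflects the orbital-free engine and the uncalibrated default
widths, so treat it as a model output, not a literature-comparable number.

Width calibration against reference interaction energies:

```r
geoms <- generate_dimer_scan(2.5, 4.5, n_points = 6, cell_edge = 7.5)
prob  <- width_fit_problem(geoms, cutoff = 20)
prob$reference <- c(...)                  # kcal/mol, one per configuration
fit   <- fit_widths(prob)
fit$par                                   # sigma_q_O, sigma_q_H, sigma_mu_O, sigma_mu_H
```

A thin command-line wrapper is installed at `exec/dfqmmm` inside the
package directory (`system.file("exec", "dfqmmm", package = "dfqmmm")` —
note `exec/` installs without the `inst/` prefix at the top level of the
installed package):

    dfqmmm run config.yaml
    dfqmmm dimer-scan --rmin 2.3 --rmax 7.7 --n 5 --out scan.tsv
    dfqmmm scan --config config.yaml --sizes 0,1,2
    dfqmmm fit-sigma fit.yaml

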