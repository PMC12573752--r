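Package: dfqmmm
Title: Density-Functionalized QM/MM with Orbital-Free Embedding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Hybrid quantum mechanics/molecular mechanics (QM/MM) in which the
    classical subsystem is assigned a smooth electron density: permanent point
    charges and induced point dipoles of a polarizable force field are mapped
    onto normalized Gaussians and Gaussian gradients, and the QM-MM interaction
    is evaluated with orbital-free nonadditive density functionals (Thomas-Fermi,
    von Weizsacker and GGA kinetic functionals plus PBE exchange-correlation)
    on a periodic real-space grid.  QM and MM subsystems are polarized to mutual
    self-consistency.  Includes a plane-wave-grid Poisson solver, an orbital-free
    DFT ground-state solver, a minimal polarizable three-site water model,
    Gaussian-width calibration against reference interaction energies, partition
    statistics for fragment-boundary errors, and generators for water dimer,
    cluster and bulk-box test systems.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
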