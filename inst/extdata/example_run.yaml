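# Example dfqmmm run configuration: hydrogen-bonded water dimer,
# donor monomer QM, acceptor monomer polarizable MM.
# Run from the directory containing the geometry file:
#   dfqmmm run example_run.yaml
system:
  geometry: water_dimer_2.9A.xyz
grid:
  cutoff: 20            # Ha
functionals:
  kinetic_additive: TFvW
  kinetic_nonadditive: GGA
  mu_k: 0.23889
  kappa_k: 1.245
mm_model:
  q_O: -0.8476          # e
  q_H: 0.4238
  alpha_O: 8.84         # bohr^3
  alpha_H: 1.98
  thole_a: 0.39
  k_SE_O: 0.0           # Ha/(e bohr)^2
  k_SE_H: 0.0
scf:
  tol_energy: 1.0e-8    # Ha/atom
  tol_density: 1.0e-6   # electrons (L2)
  max_outer: 40
  mix: 0.8
output:
  prefix: dimer
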