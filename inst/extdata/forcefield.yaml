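# One-bead-per-residue coarse-grained force field (HPS-family defaults).
# Units: nm, kJ/mol, elementary charges, Da. lambda is the dimensionless
# hydropathy in [0, 1] scaling the Ashbaugh-Hatch pair attraction.
# The per-residue table can be replaced wholesale to load other published
# parameter sets without code changes.
version: 1
global:
  bond_b0: 0.38          # nm, harmonic bond length
  bond_k: 2000.0         # kJ mol-1 nm-2
  epsilon: 0.8368        # kJ mol-1 (0.2 kcal/mol) pair interaction strength
  eps_r: 80.0            # relative dielectric of the implicit solvent
  kappa: 1.27            # nm-1, inverse Debye length at 150 mM, 300 K
  cutoff: 1.5            # nm, nonbonded cutoff
beads:
  A: {charge:  0, lambda: 0.730, sigma: 0.504, mass:  71.0788}
  R: {charge:  1, lambda: 0.000, sigma: 0.656, mass: 156.1875}
  N: {charge:  0, lambda: 0.432, sigma: 0.568, mass: 114.1038}
  D: {charge: -1, lambda: 0.378, sigma: 0.558, mass: 115.0886}
  C: {charge:  0, lambda: 0.595, sigma: 0.548, mass: 103.1388}
  Q: {charge:  0, lambda: 0.514, sigma: 0.602, mass: 128.1307}
  E: {charge: -1, lambda: 0.459, sigma: 0.592, mass: 129.1155}
  G: {charge:  0, lambda: 0.649, sigma: 0.450, mass:  57.0519}
  H: {charge:  0, lambda: 0.514, sigma: 0.608, mass: 137.1411}
  I: {charge:  0, lambda: 0.973, sigma: 0.618, mass: 113.1594}
  L: {charge:  0, lambda: 0.973, sigma: 0.618, mass: 113.1594}
  K: {charge:  1, lambda: 0.514, sigma: 0.636, mass: 128.1741}
  M: {charge:  0, lambda: 0.838, sigma: 0.618, mass: 131.1926}
  F: {charge:  0, lambda: 1.000, sigma: 0.636, mass: 147.1766}
  P: {charge:  0, lambda: 1.000, sigma: 0.556, mass:  97.1167}
  S: {charge:  0, lambda: 0.595, sigma: 0.518, mass:  87.0782}
  T: {charge:  0, lambda: 0.676, sigma: 0.562, mass: 101.1051}
  W: {charge:  0, lambda: 0.946, sigma: 0.678, mass: 186.2132}
  Y: {charge:  0, lambda: 0.865, sigma: 0.646, mass: 163.1760}
  V: {charge:  0, lambda: 0.892, sigma: 0.586, mass:  99.1326}
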