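---
title: "Models and methods in idrsuite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in idrsuite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrsuite)
```

idrsuite characterizes intrinsically disordered protein regions (IDRs) that
undergo liquid-liquid phase separation (LLPS), combining sequence
composition analysis, a coarse-grained droplet simulator, intermolecular
contact statistics, and solution-state (SAXS/CD) analysis. This vignette
explains the models, their assumptions, the tunable parameters, and the
design choices where the methodology was genuinely open.

## Sequence categorization and profiles

Residues are partitioned into five groups: cations (R, K), anions (D, E),
aromatic (F, Y, W), aliphatic (A, C, I, L, M, P, V) and hydrophilic
(G, N, S, H, Q, T). Two consequences of this partition are worth noting:
histidine is treated as hydrophilic and uncharged (a reasonable
approximation near neutral pH), and proline counts as aliphatic. The
combined "charged + polar" fraction is the sum of the cation, anion and
hydrophilic fractions; for Ser/Thr-rich, charge-depleted transactivation
domains this fraction is around 0.9.

Sliding-window profiles report windowed means of Kyte–Doolittle hydropathy,
formal charge (R, K = +1; D, E = −1; H = 0) and the fraction of residues in
the low-complexity polar set {S, T, N, Q, G, P}. Windows shrink at the
termini rather than padding: padding would invent sequence, and a shrinking
window keeps every reported value a true average of real residues (at the
cost of higher variance near the ends). The hydropathy scale is an argument,
so other scales can be substituted; the scale name is recorded in the
profile's attributes.

## The coarse-grained model

Each residue is one bead. The energy has three terms:

* **Bonds**: harmonic, `E = k/2 (r − b0)^2` with `b0 = 0.38` nm (the
  Cα–Cα virtual bond length) and `k = 2000 kJ mol⁻¹ nm⁻²` — stiff enough
  to hold the backbone geometry, soft enough for a 20 fs timestep
  (the bond period is ≈ 35 integration steps for an average residue mass).
* **Short range**: an Ashbaugh–Hatch form. With
  `σij = (σi+σj)/2`, `λij = (λi+λj)/2` and the Lennard-Jones kernel
  `Φ = 4ε[(σ/r)¹² − (σ/r)⁶]`, the potential is `Φ + (1−λij)ε` inside the
  minimum (`r ≤ 2^(1/6)σ`) and `λij Φ` outside. λ ∈ [0, 1] is a per-residue
  hydropathy that scales the attractive well while leaving the excluded
  volume intact. `ε = 0.8368 kJ mol⁻¹` (0.2 kcal/mol).
* **Electrostatics**: Debye–Hückel screened Coulomb,
  `E = f_C qi qj exp(−κr)/(εr r)`, `f_C = 138.935 kJ mol⁻¹ nm e⁻²`,
  with integer charges (R, K = +1; D, E = −1; H = 0), `εr = 80`, and
  `κ = 1.27 nm⁻¹`, the analytic value for 150 mM monovalent salt at 300 K
  (`debye_kappa()` computes it from first principles).

The per-residue table (σ, λ, charge, mass) ships as a YAML parameter file
(`inst/extdata/forcefield.yaml`) holding standard HPS-family values; the
whole table is loadable/replaceable at run time, so any published
one-bead-per-residue parameter set can be dropped in without code changes.
The nonbonded cutoff is 1.5 nm (≈ 2.4 mean bead diameters; the truncated
attractive tail is below 2% of kT per pair), chosen as the shortest cutoff
that leaves the cohesive energetics essentially unchanged while keeping
neighbor lists small. Bonded (1–2) pairs are excluded from the nonbonded
terms. True residue masses are used; this affects only the dynamics, not
equilibrium averages.

## Integration and temperature/pressure control

Dynamics are Langevin, integrated with the BAOAB splitting at a 20 fs
timestep; friction is `1/τ_t` with `τ_t = 100 ps` by default. With zero
friction BAOAB reduces to velocity Verlet, and the test suite checks total
energy conservation in that limit (two-bead bonded system, 10⁴ steps, <1%
drift). The temperature contract — time-averaged kinetic temperature within
3% of the target — is what the thermostat choice must satisfy; a literature
protocol that pairs "Langevin dynamics" with a Nosé–Hoover thermostat is
internally ambiguous, and either implementation satisfies the same
contract. We chose Langevin because it is also ergodic for the small desk-
scale systems used in testing.

The NPT stage uses Berendsen weak coupling: each step the box and all
coordinates are scaled by `μ = [1 − (dt/τ_p) β (P0 − P)]^(1/3)` with the
instantaneous virial pressure, `τ_p = 10 ps`, `P0 = 1 bar` and
`β = 4.5 × 10⁻⁵ bar⁻¹`. μ is clamped to [0.98, 1.02] per step for
stability. Zero compressibility reduces the stage to NVT exactly. Note that
with the physical compressibility the Berendsen response is slow by design:
at desk scale (durations × 1/1000) the box moves only a few percent, which
is why the protocol starts from a condensed configuration (below).

Energy minimization is a FIRE-type descent with a strict energy guard (any
uphill step is reverted, velocities zeroed, timestep halved), run to a
maximum force of 1 kJ mol⁻¹ nm⁻¹ or an iteration cap; hitting the cap is
reported with a warning, never silently. For dense random-coil starting
configurations the cap is typically reached with residual forces of order
10 kJ mol⁻¹ nm⁻¹, which is well inside the stability envelope of the 20 fs
Langevin integrator.

## The droplet protocol and its desk-scale behavior

`droplet_protocol()` runs: build on a regular grid → minimize → NVT 50 ns →
NPT 500 ns → re-box to 80 mM total residue density → minimize → NVT
production 3 μs, sampled every 5 ns (600 frames). A single `scale_factor`
multiplies every duration and the sampling interval, preserving the frame
count at any scale.

Two implementation decisions matter:

* **Condensed start.** Chain centers are placed on a
  `ceiling(n^(1/3))³` grid with spacing `1.6 Rg_ideal + 0.4 nm`
  (`Rg_ideal = b0 sqrt(L/6)`), i.e. the initial box already holds the
  chains at near-liquid density. The protocol's logic is to assemble the
  droplet first and then ask whether it survives in a dilute cell; at full
  scale the 500 ns NPT stage would condense a looser start as well, but at
  desk scale the Berendsen response is too slow to do that work, so the
  packing itself provides the condensed phase.
* **Cluster gathering at re-box.** The NPT end state is a periodic liquid
  that fills its box; connectivity runs through the periodic images. When
  the contents are transplanted into the large 80 mM cell, each molecule is
  first made whole across the old boundaries, then assigned the periodic
  image that brings its center of mass closest to the aggregate gathered so
  far (nearest molecule first), and the whole aggregate is recentered on
  its center of mass at the new box center. Without the gathering step,
  surface molecules are stranded one box-length away from the droplet and
  must diffuse back — a finite-size artifact that the full-scale protocol
  absorbs (small split-off clusters fuse within the first fraction of a
  3 μs run) but a 1000-fold-shortened production cannot.

The desk-scale validation uses 16 chains of 100 residues at
`scale_factor = 1/1000`: an aliphatic-rich synthetic sequence must keep a
single all-chain droplet in ≥90% of production frames, while an equal-length
polyanion under the identical protocol must disperse (largest cluster below
a quarter of the chains). This contrast probes the sign and rough magnitude
of the sequence-dependence, not quantitative phase boundaries: a 3 ns
production with 1,600 beads cannot measure coexistence densities, interface
widths, or evaporation/condensation equilibria, and passing it says nothing
about the behavior of real sequences beyond what the force field encodes.

## Contact statistics

A contact is an unordered pair of beads on different molecules within
`rc = 1.0 nm` (center–center; rc is not printed in the source methodology,
so it is an explicit, stamped parameter of every output). Contacts are
counted per bead pair, not capped per molecule pair — a brute-force
all-pairs oracle in the test suite pins this semantics exactly. The
by-index map is averaged over frames, normalized by the number of
molecules, and symmetrized; the type-level reduction conserves the total
exactly; `F_int` aggregates over the 15 unordered category pairs and
normalizes by the grand total. Abundance normalization divides each
type-pair entry by `N_bead(u)·N_bead(v)` (the simple product convention,
also for u = v) before aggregating — the exact supplementary formula of the
source methodology is not public, so the convention is declared in the
output metadata. Cluster traces treat chains as graph nodes with an edge
per contacting pair; components come from igraph.

## SAXS analyses

* **Guinier**: weighted linear fit of ln I vs q² on a window iterated to
  satisfy `q_max Rg = qRg_max` self-consistently (default 1.3; use 1.0 for
  flexible chains). Exact on noiseless Gaussian curves to machine
  precision. On flexible-chain (Debye-like) curves any finite window gives
  a systematic low bias of a few percent; `order = 2` adds a q⁴ curvature
  term to the log-linear model (Rg still reported from the q² coefficient),
  which removes the bias at qRg ≤ 1.3 — on 1%-noise synthetic chain curves
  the corrected fit recovers Rg to about 1% RMS, matching the Debye fit.
* **Dimensionless Kratky**: `(qRg, (qRg)² I/I0)`; for an ideal Guinier
  scatterer the analytic maximum is at `x = √3` with height `3/e ≈ 1.104`,
  the globular reference point; flexible chains instead rise to a plateau
  of 2.
* **Debye chain fit**: `I = I0·2(e^(−x) − 1 + x)/x²`, `x = (qRg)²`, by
  Levenberg–Marquardt (minpack.lm) seeded from the Guinier fit.
* **p(r) / IFT**: smoothness-regularized least squares on a fixed r-grid
  (201 points) with endpoint zeros enforced by construction. The
  regularization weight is `α` relative to the data term (default 1e-2,
  scaled by the trace ratio of the normal and penalty matrices).
  Uncertainties are floored at 0.1% of the maximum intensity so that
  near-zero-intensity points (where multiplicative noise models produce
  vanishing σ) cannot dominate the weighted fit. The Dmax search scans a
  grid, keeps candidates whose χ² is statistically indistinguishable from
  the best, and returns the smallest of them whose p(r) is essentially
  non-negative: a too-small Dmax forces large negative lobes, a too-large
  one only adds tail wiggle. On noiseless sphere curves this recovers
  `Dmax = 2R` within 5% and the analytic `Rg = sqrt(3/5) R` within 2%;
  with realistic noise Dmax softens (the p(r) tail of a compact particle
  holds <1% of the mass), which is the familiar softness of experimental
  Dmax estimates.
* **Molecular weight**: `Vc = I(0)/∫ q I dq` with Guinier extrapolation to
  q = 0; the mass estimate uses the standard `QR = Vc²/Rg` calibration
  (0.1231, exponent 1, Å units). The truncated-Porod branch integrates
  `∫q²I dq` up to the largest q with `I(0)/I(q) ≤ 10^2.25` — the
  intensity-ratio reading of that truncation rule, flagged in the output —
  and converts the Porod volume at 0.825 kDa nm⁻³. All calibration
  constants live in a `mw_calibration()` object, never inline.
* **Theoretical scattering** of conformer ensembles uses the Debye double
  sum with unit point-bead form factors, computed through a binned
  pair-distance histogram (0.01 nm bins); `I(0) = N²`.

## CD spectra

Raw ellipticities (mdeg) convert to mean residue ellipticity as
`[θ] = θ_mdeg · MRW / (10 · c[mg/mL] · l[cm])` (path metadata is stored in
mm and converted internally); `Δε = [θ]/3298`. The subtraction of a
two-domain construct's spectrum and its folded-domain-only counterpart
yields the theoretical spectrum of the disordered region; in
residue-weighted mode `(n_a·a − n_b·b)/(n_a − n_b)` the result is a true
per-residue spectrum of the difference region, which is the documented
default (the residue counts of the actual purified constructs, including
tags, are parameters — never guessed). Grid mismatches are resolved by
linear interpolation onto the coarser grid and flagged. TFE titrations are
summarized by the 222 nm and 208 nm signals per titration point;
monotonicity of |θ222| is reported, not enforced, because intermediate TFE
concentrations can scatter light (e.g. through condensation) and break
monotonicity in real data.

## Synthetic data and what passing tests mean

All generators are pure functions of their parameters and seed, and store
their ground truth beside the data. The sequence generator draws i.i.d.
residues from a composition (the `tad_like` preset is a synthetic
Ser/Thr-rich, ~5%-charged composition, not any real protein's sequence);
real IDRs have positional structure (motifs, charge patterning) that i.i.d.
draws do not reproduce. Chain ensembles are freely-jointed chains — the
ideal-chain `⟨Rg²⟩ = N b²/6` makes them an analytic oracle, but they lack
excluded volume. Scattering curves are exact analytic models with
multiplicative Gaussian noise; real detector noise is additive at high q.
CD bases are Gaussian-band constructions, not literature basis sets.
Passing the recovery tests therefore demonstrates correctness of the
estimators under their stated models, not robustness to every artifact of
real measurements.

## Problem sizes used in the shipped checks

The test suite runs the droplet contrast at 16 × 100 residues with
durations scaled by 1/1000 (3 ns production, 600 frames), three seeds per
fixture; estimator-recovery sweeps use 100 synthetic curves; contact-map
oracle equivalence uses 100 random systems of up to 500 beads. The full
literature-scale droplet system (120 chains × 352 residues, 3 μs) is
cluster-scale and is intentionally not part of the shipped checks; the
pipeline accepts it unchanged (`scale_factor = 1`, `n_copies = 120`).

## Known limitations

* The force-field parameter values are a standard HPS-family set, not the
  specific recalibrated one-bead-per-residue tables of any particular
  publication; the parameter-file mechanism exists precisely so such tables
  can be substituted.
* Berendsen pressure coupling does not sample the true NPT ensemble; it is
  used only as the equilibration device the protocol prescribes.
* The IFT is validated on analytic shapes; strongly non-ideal curves
  (aggregation upturns, structure factors) are outside its design envelope.
* Desk-scale LLPS runs probe qualitative stability only, as discussed
  above.
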