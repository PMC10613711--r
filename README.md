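# idrsuite

Tools for characterizing intrinsically disordered protein regions (IDRs) that
drive liquid-liquid phase separation (LLPS), built around the solution-state
and simulation workflow used to study low-charge, Ser/Thr-rich
transactivation domains such as the C-terminal domain of the transcription
factor HNF-1A.

The package covers four connected analyses:

1. **Sequence composition** — five-group residue categorization (cations
   R/K, anions D/E, aromatic F/Y/W, aliphatic A/C/I/L/M/P/V, hydrophilic
   G/N/S/H/Q/T), category fractions, and sliding-window profiles of
   hydropathy (Kyte–Doolittle), net charge and S/T/N/Q/G/P compositional
   bias.
2. **Coarse-grained droplet simulation** — a one-bead-per-residue model with
   harmonic bonds, Debye–Hückel screened electrostatics
   `E = f_C q_i q_j exp(-κr)/(ε_r r)` and a hydropathy-scaled
   Ashbaugh–Hatch pair potential, integrated by BAOAB Langevin dynamics
   (20 fs timestep) with a Berendsen barostat for the NPT stage. The staged
   droplet protocol is: energy minimization (1 kJ mol⁻¹ nm⁻¹ tolerance) →
   50 ns NVT → 500 ns NPT (τ_p = 10 ps, 1 bar, compressibility
   4.5 × 10⁻⁵ bar⁻¹) → re-box to a total residue density of 80 mM
   (molecules unwrapped and gathered across periodic images, recentered on
   the center of mass) → second minimization → 3 μs NVT production sampled
   every 5 ns (600 frames). A single `scale_factor` shrinks all durations
   for desk-scale runs.
3. **Contact analysis** — intermolecular contact maps by residue index
   (frame-averaged, normalized by the number of molecules), reduction to
   residue-type maps with per-type bead abundances `N_bead`, interaction
   fractions `F_int` over the 15 unordered category pairs (optionally
   abundance-normalized), and per-frame cluster-size traces from the
   chain-contact graph.
4. **Solution-state analysis** — SAXS: Guinier fits (self-consistent
   `qRg` window), dimensionless Kratky transforms with the globular
   reference maximum at `(√3, 3/e ≈ 1.104)`, Debye ideal-chain fits,
   regularized indirect Fourier transform for `p(r)`/`D_max`, and
   molecular-weight estimates via the volume of correlation
   `V_c = I(0)/∫qI(q)dq` and a truncated-Porod rule cut at
   `I(0)/I(q_max) = 10^2.25`. SRCD: mean-residue-ellipticity conversion,
   residue-weighted spectral subtraction (e.g. DBD-TAD − DBD → theoretical
   TAD spectrum), and TFE titration summaries.

Seeded synthetic-data generators (`gen_idr_sequence`, `gen_chain_ensemble`,
`gen_saxs_curve`, `gen_cd_spectra`) produce every input class with stored
ground truth, so the whole pipeline is testable offline.

## Worked example

A desk-scale droplet run with an aliphatic-rich 100-residue synthetic IDR
(16 chains, all durations scaled by 1/1000):

```r
library(idrsuite)

ff  <- read_forcefield()                      # HPS-family bead parameters
seq <- gen_idr_sequence(100, composition_preset("aliphatic_rich"), seed = 1)
cfg <- protocol_config(scale_factor = 1/1000, seed = 1)
res <- droplet_protocol(seq, n_copies = 16, ff, cfg)

res$production
#> cg_trajectory [production]: 600 frames, 1600 beads, t = 0.005..3 ns

tr <- cluster_trace(res$production, rc = 1.0)
mean(tr$largest == 16)        # fraction of frames with one all-chain droplet
#> [1] 1

cmap <- contact_map_by_index(res$production, rc = 1.0)
fint <- interaction_fractions(reduce_by_type(cmap))
head(fint[order(-fint$f_int), ], 3)
#>    category_a  category_b      f_int
#> 10  aliphatic   aliphatic 0.77
#> 14  aliphatic hydrophilic 0.21
#> 15 hydrophilic hydrophilic 0.014
```

The aliphatic-rich fixture keeps a single 16-chain droplet through the
production run, with aliphatic–aliphatic contacts carrying most of the
interaction fraction; an equal-length polyanion run under the identical
protocol disperses instead. Scattering analysis of a synthetic
disordered-chain curve:

```r
cv <- gen_saxs_curve("debye_chain", list(I0 = 1, Rg = 4.9),
                     q = seq(0.015, 2.5, by = 0.005), noise = 0.01, seed = 29)
guinier_fit(cv, qRg_max = 1.0)
#> Guinier fit: Rg = 4.775 nm, I(0) = 1
#>   window: q in [0.015, 0.21] nm^-1 (40 points, qRg <= 1.00)
debye_chain_fit(cv)
#> Debye chain fit: Rg = 4.900 nm, I(0) = 0.9995 (|res| = 0.0716)

# the finite Guinier window is biased low on flexible chains; the
# curvature-corrected variant removes the bias
guinier_fit(cv, order = 2)$Rg
#> [1] 4.942725
```

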