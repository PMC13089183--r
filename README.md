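# rssmet

Analysis pipeline for the enzymology and structural modelling of reactive
sulfur species (RSS) methylation by thiopurine S-methyltransferase (TPMT).
TPMT transfers the methyl group of S-adenosylmethionine (SAM) to thiol,
persulfide, and selenol nucleophiles; this package implements the
computational analyses used to characterize that chemistry:

1. **Enzyme kinetics.** Single-substrate Michaelis–Menten fitting by bounded
   nonlinear least squares, catalytic efficiencies `V_max / K_m` (with rates
   in nmol/min·mg and concentrations in µM the ratio is numerically
   L/min·g), and a piecewise *dual* Michaelis–Menten model for reactions in
   which added sulfide is converted in situ to glutathione persulfide (GSS⁻)
   up to a breakpoint concentration `C1`:

   ```
   v0(S) = v0_GSS(S) + v0_H2S(S)
   v0_GSS(S) = MM(S; Km_GSS, Vmax_GSS)        if S <  C1
             = MM(C1; Km_GSS, Vmax_GSS)       if S >= C1
   v0_H2S(S) = 0                              if S <  C1
             = MM(S - C1; Km_H2S, Vmax_H2S)   if S >= C1
   ```

   With the branch parameters fixed from single-substrate experiments,
   `fit_c1()` estimates the single remaining parameter `C1` by least squares.

2. **Conformational energetics.** Identification of stable ligand-binding
   conformations from fragment pair-interaction-energy (PIE) matrices
   (conformations × fragments, kJ/mol): per-conformation totals
   `Σ_j Σ_i PIE_ij`, per-fragment (per-residue) contribution profiles,
   agglomerative clustering (Ward on Euclidean distances), Tukey–Kramer
   all-pairs comparison of per-cluster total PIEs with a compact letter
   display, selection of the statistically indistinguishable
   strongest-binding cluster set, and the binding-energy bookkeeping
   `ΔG_bind = E_complex − (E_receptor + E_ligand)`.

3. **Steric attack geometry.** Per-frame nucleophilic-attack geometry from
   trajectory coordinates: the nucleophile–C_SAM distance, the alignment
   angle θ (at the SAM methyl carbon, between the SAM sulfur and the
   nucleophile; near 180° = in-line attack), and the hindrance angle φ (at
   the nucleophile, between its substituent and C_SAM). Reaction-competent
   frames (distance ≤ 4 Å, θ in [150°, 180°]) are extracted and scored by
   the fraction with φ in the sterically optimal range [100°, 180°].

A synthetic-data module (`gen_mm_rates()`, `gen_dual_mm_rates()`,
`gen_pie_matrix()`, `gen_trajectory()`) generates all three input families
with known ground truth, so every stage is testable without wet-lab data, MD
engines, or quantum-chemistry packages.

## Worked example

```r
library(rssmet)

# Simulate noiseless initial rates at the assay design concentrations from
# the published disulfide parameters, then refit them:
d <- gen_mm_rates(mm_truth(km = 331, vmax = 260),
                  kinetic_design(c(20, 200, 2000), n_rep = 1, noise_sd = 0))
fit_mm(d)
#> MM fit: Km = 331 uM, Vmax = 260 nmol/min/mg, Vmax/Km = 0.7855 L/min/g
#>   residual SS = 0 over 3 observations (converged: TRUE)
```

The fitted efficiency 0.7855 L/min·g matches the published 0.78 for the
disulfide substrate. The full workflow lives in `analysis/01_simulate.R`
through `analysis/04_geometry.R`; running them in order prints, among other
things:

```
Breakpoint fit: C1 = 50.01 uM (planted 50 uM), residual SS = 5.328
Stable clusters: 1, 2, 3, 4 (planted: 4 strong clusters of 20 conformations)
unhindered: 1688/2000 frames reaction-competent; optimal-phi fraction 99.1%
hindered  : 1702/2000 frames reaction-competent; optimal-phi fraction 4.6%
```

i.e. the breakpoint fit recovers the planted `C1`, the clustering recovers
the planted stable-conformation set, and the φ scoring separates an
unhindered (persulfide-like, φ centred at 135°) from a hindered
(methylselenide-like, φ centred at 75°) attack geometry. Tables and JSON
result envelopes are written under `results/`.

`run_pipeline(demo_config())` runs the same four stages end to end from a
single configuration list (or YAML file) with one master seed.

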