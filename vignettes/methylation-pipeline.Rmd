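---
title: "Kinetic, energetic, and geometric analysis of RSS methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic, energetic, and geometric analysis of RSS methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rssmet)
```

This vignette is the package's account of the models it implements, the
choices made where the design was genuinely open, and what the synthetic-data
tests do and do not establish about real data.

## The scientific setting

Thiopurine S-methyltransferase (TPMT) methylates reactive sulfur species —
hydrosulfide (HS⁻), hydrodisulfide (HSS⁻), glutathione persulfide (GSS⁻) —
and selenium analogues, transferring the methyl group of S-adenosylmethionine
(SAM) to the nucleophilic sulfur or selenium. Three computational analyses
characterize this chemistry and are reimplemented here: initial-rate enzyme
kinetics, identification of stable ligand-binding conformations from fragment
pair interaction energies, and steric scoring of the nucleophilic attack
geometry in trajectories.

## Kinetics

### Single-substrate model

The initial rate at substrate concentration $S$ is
$v_0(S) = V_{max} S / (K_m + S)$. `fit_mm()` minimizes the residual sum of
squares over $K_m > 0$, $V_{max} \ge 0$ with Levenberg–Marquardt under box
bounds (`minpack.lm`). Initialization is data-driven: $V_{max,0}$ is the
maximum observed rate and $K_{m,0}$ the design concentration whose mean rate
is nearest $V_{max,0}/2$; two further starts at $K_{m,0}/4$ and $4K_{m,0}$
guard against the shallow-$K_m$ pathology when the design barely saturates
the enzyme. Zero-concentration rows are retained as blank anchors — the
model passes through the origin, so they constrain the noise floor without
biasing parameters. Degenerate input with all rates zero returns
$V_{max} = 0$ with $K_m$ flagged unidentifiable instead of erroring.

The catalytic efficiency is $V_{max}/K_m$; with rates in nmol·min⁻¹·mg⁻¹ and
concentrations in µM the ratio is numerically L·min⁻¹·g⁻¹. Efficiencies are
computed at full precision; published tables print them at one or two
significant figures (e.g. 16.2/15.5 = 1.045 prints as 1.0).

### Dual-substrate model with breakpoint C1

When sulfide is added in the presence of glutathione, the species actually
methylated below a breakpoint concentration $C_1$ is the in-situ-formed
persulfide; the excess above $C_1$ reacts as free H₂S. The apparent rate is

$$v_0^{app}(S) = v_0^{GSS}(S) + v_0^{H2S}(S),$$

with $v_0^{GSS}(S) = MM(S)$ below $C_1$ and frozen at $MM(C_1)$ above it, and
$v_0^{H2S}(S) = MM(S - C_1)$ above $C_1$ and zero below. The model is
continuous at $S = C_1$ (the H₂S branch starts from zero) and nondecreasing
in $S$; both properties are tested on random parameter draws.

`fit_c1()` treats the two branch parameter pairs as fixed constants — they
are estimated beforehand from the persulfide-only and sulfide-only
experiments — and fits the single parameter $C_1 \in [0, \max S]$. The
objective is piecewise smooth with kinks possible at data concentrations, so
a 512-point grid scan brackets the basin, golden-section search refines it
(default tolerance 10⁻⁶ µM), and both interval endpoints are checked
explicitly so boundary solutions ($C_1 = 0$, $C_1 = \max S$) are exact. A
joint 5-parameter refit is deliberately not the default: fixing the branches
mirrors how the experiment determines them.

## Conformational energetics

A PIE matrix holds pair interaction energies $PIE_{i,j}$ (kJ/mol) between a
ligand and each fragment of the receptor/SAM complex, one row per sampled
conformation. The per-conformation total $\sum_j \sum_i PIE_{i,j}$ measures
the ligand's overall interaction with the complex (more negative = stronger);
per-fragment sums rank binding-site residues.

`cluster_conformations()` clusters rows by hierarchical agglomeration on
Euclidean distances. Ward linkage is the default (complete and average are
exposed): the published analyses name only "agglomerative clustering", and
Ward's variance criterion matches the goal of compact energy-profile groups.
Features are the raw PIE rows — all columns share units (kJ/mol), so
standardization is unnecessary by default and available as a user
transformation. The partition comes from the dendrogram: an explicit cluster
count, an explicit cut height, or (default) the cut at the largest relative
gap between consecutive merge heights, capped at 12 clusters. Published
cluster counts (e.g. nine for one ligand, seven for another) depend on the
original trajectories and are not reproducible targets; what is testable is
exact recovery (adjusted Rand index 1) of well-separated planted partitions.

`tukey_kramer()` compares per-cluster totals with the studentized-range
statistic valid for unequal group sizes: pooled within-group variance $s^2$
on $N - k$ degrees of freedom and
$q_{ab} = |\bar{x}_a - \bar{x}_b| / \sqrt{(s^2/2)(1/n_a + 1/n_b)}$, with
p-values from the studentized range distribution. Two-group results agree
with the classical Tukey HSD, and the family-wise type-I error under the
null is verified by simulation to stay at or below $\alpha$. With zero
pooled variance, comparisons reduce to exact mean equality. The compact
letter display uses the insert-and-absorb construction — start from one
letter covering all clusters, split on each rejected pair, absorb redundant
columns — so clusters share a letter exactly when not significantly
different; letters are ordered by ascending mean total PIE, i.e. letter "a"
marks the strongest-binding group.

`select_stable_clusters()` returns every cluster whose letter set equals
that of the cluster with the most negative mean total: the statistically
indistinguishable strongest-binding set. This reproduces the reporting
convention in which several clusters are jointly called stable.
`delta_g_bind()` implements the bookkeeping identity
$\Delta G_{bind} = E_{complex} - (E_{receptor} + E_{ligand})$; the quantum
energies themselves are consumed, never computed.

## Steric attack geometry

For each frame, `frame_geometry()` reports the nucleophile–C_SAM distance
$d_1$, the substituent–C_SAM distance $d_2$, their difference, the alignment
angle $\theta$ (at the SAM methyl carbon, between the SAM sulfur and the
nucleophile — near 180° means the nucleophile sits in line for backside
attack), and the hindrance angle $\varphi$ (at the nucleophile, between its
substituent and C_SAM — values in [100°, 180°] leave the lone pair
unobstructed). For a persulfide the nucleophile/substituent pair is
S₁ (deprotonated) / S₂; for methylselenide the analogous definition
(methyl carbon – Se – C_SAM) is used — the source analyses never state the
selenide $\varphi$ explicitly, and this analogy is the one open
interpretation the module takes. $\theta$ for the substituent is computed and
reported but never used in filtering.

Angles are evaluated as `atan2(|u × v|, u · v)`, which keeps full precision
near 0° and 180° where the arccosine form loses half the significant digits;
this is what makes the 10⁻⁹-degree round-trip test against the generator
possible. All cutoffs are inclusive: extraction keeps frames with
$d_1 \le$ 4 Å and $\theta \in$ [150°, 180°]; the optimal range is
$\varphi \in$ [100°, 180°]. The $\varphi$ histogram bins [0°, 180°) at 10°
(any divisor of 180 is accepted) with the last bin closed, so counts always
sum to the extracted frames. An empty extraction yields an undefined (NA)
optimal fraction, never 0%. Inputs are multi-frame XYZ in Å or a per-frame
geometry table; nm coordinates are rescaled via `scale = 10`. Engine-native
trajectory formats are intentionally not parsed.

## The synthetic-data module

The generators define the study conditions under which everything is tested:

* **Kinetics** — design points 0, 20, 200, 2000 µM with 3 replicates (the
  assay layout), additive homoscedastic Gaussian rate noise. The source
  experiments report neither replicate counts nor the luminescence error
  model; 3 replicates and a noise SD of 5% of $V_{max}$ were chosen once as
  typical of plate-based methyltransferase assays. Heteroscedastic noise is
  a known omission.
* **PIE matrices** — planted cluster mean profiles plus independent Gaussian
  within-cluster noise, with true labels returned. This emulates the
  *statistical* structure of conformations sampled by simulated-annealing
  MD, not its physics: real PIE rows are autocorrelated along the
  trajectory, cluster shapes need not be spherical, and energies are not
  Gaussian. Passing recovery tests therefore certifies the clustering and
  testing machinery, not force-field accuracy.
* **Trajectories** — frames constructed to realize sampled $(d, \theta,
  \varphi)$ exactly (C_SAM at origin, S_SAM along an axis at the 1.81 Å S–C
  bond length, substituent at 2.05 Å with a random dihedral), then given a
  random rigid-body pose per frame so frame-invariance is a real test.
  Truncated-normal and uniform angle distributions are supported; truncation
  is by resampling, preserving shape on [0°, 180°]. The hindered/unhindered
  contrast (φ centred at 75° vs 135°, matched 15° widths) qualitatively
  reproduces the published steric separation between methylselenide and
  persulfide; the published percentages themselves derive from MD
  trajectories that cannot be regenerated here.

All generators are bit-reproducible from an integer seed, and the pipeline
(`run_pipeline()`) derives per-stage seeds from one master seed.

## Problem sizes and numerical tolerances

The test suite and analysis scripts run at desk scale by design: 200
replicates for the $K_m$ bias bound, 1000 null simulations for the
family-wise error check, 10⁵ frames for the uniform-φ fraction (analytic
value 80/180 = 44.4%), 120 conformations for the planted stable-set
recovery. Noiseless fits are required to recover parameters to a relative
10⁻⁶; the breakpoint to 0.1 µM; geometry round-trips to 10⁻⁹ in Å and
degrees; PIE conservation (fragment sums vs conformation sums) to a relative
10⁻⁹.

## Known limitations

* The kinetic noise model is additive and homoscedastic; real luminescence
  assays are closer to constant-CV.
* The automatic dendrogram cut (largest relative merge-height gap) is a
  heuristic; for irregular cluster-size spectra an explicit `n_clusters` or
  `cut_height` is preferable.
* The compact letter display is the minimal insert-and-absorb cover; it does
  not attempt letter minimization beyond absorption.
* No PBC unwrapping, solvent handling, or engine-format parsing: coordinates
  are assumed whole-molecule and unwrapped, in XYZ or a geometry table.
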