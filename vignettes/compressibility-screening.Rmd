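---
title: "Compressibility-guided mutant screening: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressibility-guided mutant screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhpmd)
```

## The model

Proteins in water–ethanol mixtures under elevated pressure expose their
mechanically soft regions: where the local structure responds to pressure,
its volume fluctuates more. `dhpmd` operationalizes this through the
equilibrium fluctuation relation for the isothermal compressibility,

$$\langle \delta V^2 \rangle = k_B \, T \, \langle V \rangle \, \beta_T ,$$

applied per region and per condition of a pressure × ethanol grid. Region
volumes come from an ordinary (unweighted) Voronoi tessellation of every
snapshot over **all** atoms, protein and solvent alike, so that
protein–solvent boundaries are physical; a region's volume is the sum of
its heavy atoms' cells. Regions whose $\beta_T$ varies most across the
grid ("sensitive fluctuation" regions) are assumed to be the ones whose
stability limits performance in ethanol, and all 19 substitutions at each
of their positions are scored by two external stability predictors with
opposite sign conventions. Only the double consensus
($\Delta\Delta G_A < 0$ and $\Delta\Delta G_B > 0$, both strict) survives.

The package computes every step after the molecular dynamics itself: it
consumes multi-model PDB or GRO snapshots and predictor score tables, and
never launches an MD engine or predictor binary.

## Key parameters

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| temperature | 313 | K | assay and simulation temperature of the reference system |
| pressures | 1, 500, 1000 | bar | reference condition grid |
| ethanol fractions | 0.10, 0.50, 1.00 | v/v | reference condition grid |
| parallels × run length | 5 × 30 | – × ns | reference design (45 runs, 1350 ns) |
| sampling interval | 1 | ns | snapshot spacing used for volume series |
| $k_B$ | 1.380649e-23 | J/K | exact SI |
| variance convention | population (÷ n) | – | ensemble-average convention; `variance = "sample"` switches to n−1 |
| sensitivity score | max−min of $\beta_T$ | bar⁻¹ | absolute range across the grid; `relative = TRUE` uses range/mean |
| solvent-count cutoff | 5.0 | Å | typical first+second hydration shell; a 3–8 Å sweep is provided because counts depend on it |
| H-bond criteria | 3.5 Å, 30° | – | common geometric defaults |
| SASA probe, points | 1.4 Å, 960 | – | water probe; 960 golden-spiral points give <1% error vs closed forms |
| vdW radii | C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, Na 2.27 | Å | Bondi-style table, overridable |
| consensus thresholds | 0 / 0, strict | kcal/mol | the filter's defining inequalities |

Units are fixed internally: coordinates in Å (GRO input converted from nm
on read), volumes in Å³, $\beta_T$ reported in bar⁻¹ (1 Pa⁻¹ = 10⁵ bar⁻¹)
because the pressure grid is in bar; `unit = "Pa"` is available.

## Numerical choices

**Voronoi under periodicity.** Each site's cell is obtained by half-space
clipping: the site-centred half-box cuboid (the bisector constraint
against the site's own periodic images) is cut by the bisector planes of
every other site's 27 periodic images, nearest first, stopping when no
remaining plane can reach the current polyhedron. This makes conservation
($\sum$ cells = box volume) hold to machine precision, which the tests
assert at 10⁻⁶ relative tolerance, and is cross-checked against
Monte-Carlo nearest-site integration. Coincident sites are an error naming
the pair; a warning fires when a site's nearest neighbour is further than
half a box edge, since such cells are bounded by their own images. Only
orthorhombic boxes are supported; triclinic input is an explicit error.

**Secondary structure.** The built-in assignment is a P-SEA-style φ/ψ
window heuristic (helix: φ ∈ [−90, −30], ψ ∈ [−77, −17]; sheet:
φ ∈ [−170, −90], ψ ≥ 90 or ≤ −170; otherwise loop), with helix runs
shorter than 4 and sheet runs shorter than 3 demoted to loop and chain
termini inheriting their neighbour's class. An external one-letter
H/E/C file is preferred when a dedicated assignment tool has been run,
keeping results auditable. Segment names follow the `loop_67-76`
convention: 1-based, inclusive, 10 residues.

**Superposition and RMSF.** Kabsch least-squares fitting (proper rotations
only) over Cα atoms by default, reference = first frame; RMSF uses the
population mean over frames. Neither choice is prescribed by the screening
design, so both are stated and switchable.

**Michaelis–Menten fitting.** Levenberg–Marquardt least squares of
$v = V_{max} S/(K_m+S)$ with $V_{max,0} = \max v$ and $K_{m,0}$ the level
nearest half-maximum; a fitted $K_m$ outside $(0, 10\,\max S)$ is flagged
unreliable. Catalytic efficiency is reported as $k_{cat}$ (s⁻¹) divided by
$K_m$ in mM, because tabulated efficiencies for this assay equal that
ratio numerically even when labelled s⁻¹·M⁻¹; both scales are returned.
$k_{cat}$ itself is consumed from reported values rather than recomputed
from $V_{max}$, since the conversion needs the enzyme's molar mass, which
assay tables typically omit.

**Consensus filter.** Strict inequalities at zero for both predictors;
a candidate missing either score is `incomplete` and excluded from the
stabilizing subset rather than treated as zero. External predictors are
integrated by file exchange only, which keeps the pipeline hermetic and
testable.

## The synthetic-data generators

The generators stand in for the MD engine and predictor binaries so the
whole pipeline runs and is tested without external software:

- `generate_toy_protein` builds ideal-geometry N/CA/C/O backbones from
  per-segment dihedrals. The 392-residue `toy_hydrolase_layout()` fixture
  reproduces the reference system's six candidate loops (67–76, 82–107,
  176–181, 254–261, 320–333, 381–392) and `toy_hydrolase_sequence()` fixes
  the wild-type identities at the mutated positions (H68, K70, A178, A321,
  S325, Q332).
- `generate_volume_series` inverts the fluctuation relation: Gaussian
  volumes whose variance encodes a target $\beta_T$. Recovery of the
  target by `beta_t()` is the estimator's oracle (within 3% at n = 10⁴;
  the error shrinks with n as 1/√n).
- `generate_volume_trajectory` injects fluctuations geometrically, scaling
  a region's coordinates about its centroid. Because cell faces shared
  with non-scaled neighbours move only halfway, the measured volume
  responds with a gain below 1; the generator probes this linear response
  once and amplifies the injected scaling accordingly. The estimator, not
  the physics, is what such trajectories test.
- `generate_solvated_box` places 3-atom water and 3-heavy-atom ethanol
  pseudo-molecules, with exact counts inside prescribed distance bands of
  named sites and bulk molecules kept clear of those bands, so shell
  counts are exact by construction.
- `generate_kinetics_dataset` draws multiplicative Gaussian noise around
  the Michaelis–Menten curve over levels within the assay's 0–300 mM
  substrate range.
- `ddg_fixture_table` assigns seeded score magnitudes with signs fixed so
  that a prescribed mutant set is exactly the consensus outcome — it tests
  the filter's set-membership logic, not any predictor.

All generators are deterministic given their seed and restore the caller's
RNG state.

What the generators do **not** emulate: real conformational dynamics,
force-field energetics, thermodynamically consistent water–ethanol
mixtures, or predictor score distributions. Passing tests therefore
demonstrate that the estimators, filters and arithmetic are correct on
data with known ground truth — not that the screening strategy's physical
assumptions hold for any particular enzyme. Figure-level quantities of the
reference study that depend on real 30-ns trajectories (absolute RMSD/RMSF
curves, absolute per-loop $\beta_T$ values, predictor ΔΔG values, solvent
counts around the active centre) are intentionally out of scope.

## Design decisions that were genuinely open

- **Ordinary vs radical (power) Voronoi:** ordinary, since the volume
  definition cited for this strategy is the plain tessellation; radii are
  kept for SASA only.
- **Per-region volume definition:** sum of the region's heavy-atom cells
  from a tessellation over all atoms (hydrogens conceptually absorbed into
  heavy-atom cells); the scope is configurable.
- **Sensitivity score:** absolute $\beta_T$ range over all nine
  conditions. The alternative relative range (range/mean) is one flag
  away; with only "large differences" to go on, the absolute range is the
  simpler, unit-carrying choice.
- **Condition pooling:** parallels of one condition are pooled into one
  series per region × condition before estimating $\beta_T$ (the default
  synthetic config pools 5 × 30 samples); per-parallel estimation can be
  had by planning the grid with `parallels = 1`.
- **Pipeline config format:** YAML (`read_screen_config`), the R
  ecosystem's convention for such manifests.
- **CLI:** a thin Rscript (`inst/exec/dhpmd`) over the exported functions;
  the functions themselves are the primary interface.

## Problem sizes used in the test-suite

The suite runs entirely on generated data: Voronoi systems of 1–125
sites (Monte-Carlo cross-checks at 2×10⁵–10⁶ points), volume series of
30–10⁴ samples, trajectories of up to 60 frames of a ~50-atom toy protein,
the 392-residue fixture for segmentation and the 570-candidate screen,
and 200-seed Michaelis–Menten noise replicates. These sizes were chosen so
each property is measured well inside its statistical tolerance.

## Known limitations

- Orthorhombic boxes only; no insertion codes, chain breaks, or multi-chain
  topologies.
- The φ/ψ heuristic is 3-state and window-based; it is a fallback, not a
  DSSP replacement.
- The surrogate ΔΔG scorer is a seeded heuristic for exercising the
  pipeline; its scores carry no physical meaning.
- `beta_t` assumes equilibrium sampling; drifting volume series will
  inflate the variance and hence $\beta_T$.
- The Voronoi clipping is O(N) per site with a 27-image candidate list,
  comfortable for the pseudo-solvated systems generated here (hundreds to
  a few thousand sites) but not tuned for production-size solvated boxes.
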