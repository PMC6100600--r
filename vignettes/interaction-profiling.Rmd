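---
title: "Methods: geometric interaction profiling of ligand-aptamer trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometric interaction profiling of ligand-aptamer trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptaprof)
```

## The analysis model

`aptaprof` treats an MD trajectory of a ligand–aptamer complex as a series
of independent geometric snapshots. In each frame the atoms are partitioned
into receptor, ligand, explicit water and ions (by residue name, with an
element heuristic for monatomic ions), each atom is typed into functional
roles, and four interaction classes are detected by purely geometric
criteria. Trajectory-level answers — which bases bind, through which
chemistry, how often — are aggregations of these per-frame events. The
approach makes no energetic judgement at detection time; the separate MM
energy module quantifies interaction strength independently.

The underlying assumptions are worth stating plainly:

* **All-atom input.** An explicit-hydrogen trajectory is assumed
  (`strict_hydrogens = TRUE`): hydrogen-bond donors are typed from covalent
  N/O–H bonds and angle criteria use real hydrogen positions. A lenient
  heavy-atom-only mode exists for crystallographic-style input; it types
  every N/O as donor and acceptor, skips angle tests, and tags every
  downstream record, because inferring hydrogen positions would invent
  geometry.
* **Per-frame independence.** Detection in frame *t* never looks at frame
  *t−1*; lifetimes and correlations are left to the aggregation layer.
* **Topology stability.** Atom roles are assigned once on the first frame
  and reused (ring planes are refit per frame). This matches MD output,
  where connectivity never changes, and guarantees role flags cannot
  flicker between frames.

## Atom typing

Covalent bonds are inferred by distance: heavy–heavy pairs ≤ 1.9 Å, X–H
pairs ≤ 1.25 Å. This parameter-free rule is adequate for MD snapshots and
synthetic fixtures built with standard bond lengths; it is not meant for
distorted minimization intermediates. Roles follow from the bonds:

* *donor*: N or O (non-water) with ≥ 1 bonded hydrogen;
* *acceptor*: any non-water N or O (a hydroxyl oxygen is both);
* *hydrophobic carbon*: C whose bonded neighbours are all C or H;
* *aromatic member*: atom in a ring template (purine 5- and 6-rings,
  pyrimidine ring, for the standard bases under DA/DG/DC/DT/DU and
  one-letter aliases) or in a generic planar 5/6-cycle found on the ligand
  bond graph (RMS plane deviation ≤ 0.2 Å). Templates first because they
  are deterministic for bases; the generic search covers arbitrary ligands.

Hydrogens never carry heavy-atom roles.

## Detection criteria and their parameters

All thresholds live in `interaction_config()` and serialize to JSON; they
are data, not constants. The `"plip-default"` preset carries the published
PLIP criteria, the de facto standard for interaction fingerprinting:

| parameter | default | unit | meaning |
|---|---|---|---|
| `hbond_da_max` | 4.1 | Å | donor–acceptor distance cap |
| `hbond_angle_min` | 100 | ° | minimum ∠(D–H⋯A) |
| `hydrophobic_max` | 4.0 | Å | C⋯C contact cap |
| `pistack_center_max` | 5.5 | Å | ring-centroid distance cap |
| `pistack_offset_max` | 2.0 | Å | lateral centroid offset cap |
| `pistack_parallel_angle_max` | 30 | ° | plane angle for "parallel" |
| `pistack_tshape_angle_min/max` | 60–90 | ° | plane-angle window for "T-shaped" |
| `waterbridge_dist_min/max` | 2.5–4.1 | Å | both bridge legs |
| `waterbridge_omega_min/max` | 71–140 | ° | ω at the water oxygen |
| `waterbridge_theta_min` | 100 | ° | θ at the donor hydrogen |

A `"strict"` preset (D–A ≤ 3.5 Å, angle ≥ 120°) ships for sensitivity
analysis, and a `"gromacs"` preset (D–A ≤ 3.5 Å, near-linear angle) is the
default for *intramolecular* hydrogen-bond counting, mirroring the
convention of MD-suite H-bond tools so that stability counts are comparable
with simulation-package output. GROMACS itself cuts on the
hydrogen–donor–acceptor angle at the donor (≤ 30°); we state the equivalent
intent as ∠(D–H⋯A) ≥ 150° so a single H-bond engine serves all presets.
The water-bridge geometry follows the PLIP convention: θ is the
∠(D–H⋯O~w~) angle at the donor hydrogen, ω the angle at the water oxygen
between the acceptor and the donor hydrogen. The water's own hydrogen
positions are not tested — in MD water orientations relax on picosecond
timescales, and the heavy-atom geometry plus the two angle criteria already
pin down a relayed bond.

Two reduction rules prevent double counting downstream: each donor hydrogen
keeps only its nearest qualifying acceptor (ties to the lower serial), and
hydrophobic candidate pairs are reduced to one record per (receptor
residue, ligand atom) at minimum distance. Interaction classes are detected
independently — a base may legitimately appear as both a hydrogen-bond and
a hydrophobic partner in one frame, which is chemically real for bases
lining a binding pocket.

## Trajectory statistics

Rg is mass-weighted by default (MD-suite convention); RMSD uses Kabsch
superposition via SVD with a determinant correction restricting the fit to
proper rotations. The fit selection defaults to receptor heavy atoms; the
ligand can be reported without entering the fit. RMSF uses the
trajectory-mean reference after one fitting pass: every frame is superposed
on frame 1, the mean structure is formed, frames are refit onto that mean,
and RMSF is measured about the final mean. One pass is the standard
compromise; exact order-independence of the result would require iterating
to convergence, so shuffling frames reproduces RMSF to ~10⁻⁴ Å rather than
machine precision. Region tables report both the mean over member atoms and
the mean of per-residue means, since published region tables rarely say
which was used.

## Distance maps and secondary structure

Distance-map entries are minimum inter-atomic distances per residue pair;
both a heavy-atom and an all-atom metric are provided because published
base-distance maps with minima near 1.5 Å imply hydrogens were included,
while heavy-atom maps are the more common convention. Base-pair lists come
from dot-bracket or explicit pairs; crossing pairs are refused rather than
silently flattened, because for short nested aptamer structures a
pseudoknot in the input is almost certainly an error. Annotation labels
unpaired 5′/3′ runs as tails, helices as stems (a helix enclosing a
pair-free region closes a hairpin), unpaired residues inside a
hairpin-closing stem as hairpin loop, and unpaired residues flanked by
exactly one inner helix as interior loop (covering bulges); anything else —
multiloop junctions — is `unpaired-other`. Coarse labels merge hairpin stem
and loop into a single "hairpin loop" region, the convention of per-region
flexibility tables.

## Energy decomposition

The energy module computes the gas-phase molecular-mechanics interaction
energy only: Coulomb (f·q₁q₂/ε_r·r, f = 138.935485 kJ·mol⁻¹·nm·e⁻²) plus
Lennard-Jones (4ε[(σ/r)¹²−(σ/r)⁶]) over all ligand×receptor atom pairs,
grouped by receptor residue, each pair assigned wholly to its residue.
Units are GROMACS-native (nm, kJ/mol, e); coordinates in Å are converted at
the module boundary to rule out a 10× error class. Parameters are
user-supplied as a TSV (no force-field file parsing), matched strictly by
(residue name, atom name) — missing parameters fail loudly rather than
defaulting to zero charge. The polar (Poisson–Boltzmann) and non-polar
(SASA) solvation terms of a full MM/PBSA binding energy are deliberately
absent and carried as explicit `NA` markers, so a gas-phase decomposition
can never be mistaken for ΔG_binding.

## The synthetic-fixture generator

`make_complex()` is the package's ground-truth instrument, not a
physical simulator. It assembles a two-anchor diol ligand mimic (benzene
ring, hydroxyls at a "3"-like and a "17-β"-like position, an apolar chain)
and places single-purpose receptor fragments — a carbonyl acceptor, an
amine donor, a full planar thymine-like base, a pair of sugar-like carbons,
plus pivot waters — on distinct approach directions so planted interactions
never interfere. Planted geometries satisfy the default thresholds with
≥ 10 % margin (asserted numerically at build time), which keeps them robust
to the 0.001 Å truncation of PDB output; in frames where an interaction is
declared absent, its fragment is displaced 12 Å outward, violating every
window by a wide margin. Each frame then receives a seeded random
rigid-body rotation and translation, optionally with Gaussian coordinate
noise (default 0 so recovery is exact), and the seed is stamped into PDB
REMARK records. What passing planted-recovery tests shows is that the
detectors implement their geometric definitions exactly; what it does not
show is robustness to the conformational diversity, thermal disorder, and
marginal borderline geometries of real MD output, where threshold choice
genuinely changes counts.

Fixture problem sizes used by the test-suite and the acceptance analysis —
systems of roughly 60–100 atoms, 1–10 frames, dozens of random fixtures per
property, 50–100 seeds for recovery scoring, and a 200-frame fixture for
the bound-fraction computation — were chosen so that exhaustive brute-force
oracles (all-triples, all-quadruples enumeration) remain practical
cross-checks.

## Numerical choices

* Ring planes by SVD of centered coordinates; the normal is
  sign-canonicalized toward +z (ties toward +x, then +y) so plane fits are
  deterministic. Collinear input is an error, not a NaN.
* Kabsch via SVD of the covariance with det-correction; degenerate
  (collinear) selections are refused.
* Aggregation math is exact on counts; half-up rounding to two decimals is
  applied only by `format_report()` at presentation time.
* Record ordering is fixed (frame, class, residue, atom) so equal inputs
  give byte-identical TSV output.
* Frame indices are 1-based throughout the R API; residue numbering is
  preserved from the input file and never silently renumbered.

## Open choices made

* Trajectories are analyzed as provided; no re-protonation or hydrogen
  addition is attempted, so detection reflects the simulation's own
  hydrogen placement.
* Whether published per-region flexibility values are atom-level or
  residue-level means is ambiguous; both are reported.
* Per-anchor attribution of π-stacking uses the ligand ring identifier
  (rings, not hydroxyls, stack); hydroxyl-position anchors apply to
  hydrogen bonds and bridges.
* Hydrophobic contacts count in per-base totals but are excluded from the
  bound-fraction and combination shares, which are defined over specific
  interactions only.

## Known limitations

* No salt bridges, halogen bonds, cation–π or metal coordination; the four
  implemented classes are the ones relevant to neutral steroid–DNA
  binding.
* No binary trajectory formats (XTC/DCD/GRO) — multi-model PDB only, which
  any MD suite can export; the reader is an extension point.
* The energy module is not an MM/PBSA implementation and its absolute
  values depend entirely on the user-supplied parameter table.
* Exact numerical agreement with any specific published interaction count
  is not claimable from geometry alone: published profiling runs depend on
  tool versions and unprinted parameter values, which is precisely why all
  thresholds here are explicit configuration.
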