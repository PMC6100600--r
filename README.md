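# aptaprof

Geometric profiling of non-covalent interactions between a small-molecule
ligand and a single-stranded DNA aptamer across a molecular-dynamics
trajectory, in R.

Aptamers — short ssDNA/RNA oligonucleotides that fold into ligand-binding
3D structures — are promising biosensors for micro-pollutants such as
steroid hormones, but the atomic detail of how they hold their ligand is
rarely observable experimentally. The practical route is an explicit-solvent
MD simulation of the ligand–aptamer complex followed by per-frame
interaction fingerprinting: in every snapshot, detect which bases contact
the ligand and through which chemistry, then aggregate those per-frame
events into binding-site statistics over the whole simulation. `aptaprof`
implements that analysis chain for multi-model PDB trajectories, plus the
standard structural-stability readouts that accompany it.

## What it computes

**Interaction detection** (per frame, PLIP-style geometric criteria, all
thresholds configurable via `interaction_config()`):

| class | criterion (defaults) |
|---|---|
| hydrogen bond | D–A ≤ 4.1 Å and ∠(D–H⋯A) ≥ 100° |
| water-mediated H-bond | both heavy-atom legs in 2.5–4.1 Å, θ = ∠(D–H⋯O<sub>w</sub>) ≥ 100°, ω (angle at O<sub>w</sub> between acceptor and donor H) in 71–140° |
| π-stacking | ring-centroid distance ≤ 5.5 Å, lateral offset ≤ 2.0 Å, plane angle ≤ 30° ("parallel") or 60–90° ("T-shaped") |
| hydrophobic contact | C⋯C ≤ 4.0 Å between apolar carbons, reduced to one contact per (residue, ligand atom) |

Records are typed chemically (`O–H⋯O`, `N–H⋯O–H⋯O`, `parallel`, …) and
attributed to named ligand anchors (e.g. the "3" and "17-β" hydroxyl
positions of a steroid diol).

**Trajectory statistics**: radius of gyration
(Rg = √(Σmᵢ|rᵢ−r_com|²/Σmᵢ)), Kabsch-superposed RMSD series (vs a reference
frame or frame-paired against a second trajectory), per-atom RMSF with
region means, and per-frame intramolecular hydrogen-bond counts.

**Structure annotation**: minimum inter-residue distance maps
(heavy-atom or all-atom metric), dot-bracket / pair-list parsing, and
secondary-structure-element labels (5′/3′ tails, stem, interior loop,
hairpin) with 3D base-pair-formation checks against the distance map.

**Energy decomposition**: gas-phase molecular-mechanics interaction energy
(Coulomb + Lennard-Jones, GROMACS units, Lorentz–Berthelot combination)
between ligand and receptor, per receptor residue with trajectory
mean ± SEM. Solvation terms of a full MM/PBSA treatment are explicitly out
of scope and marked as not computed.

**Synthetic fixtures**: `make_complex()` builds small
receptor–ligand–water systems with planted, margin-checked interaction
geometries under rigid-body motion, so every detector can be validated
against a known ground truth without any external data.

## Worked example

```r
library(aptaprof)

spec <- fixture_spec(seed = 42, n_frames = 10,
  planted = list(plant("hbond", 1:9), plant("pistack", c(1:5, 8)),
                 plant("water_bridge", 1:10), plant("hydrophobic", 4:7)),
  n_decoy_waters = 20)
traj <- make_complex(spec)          # or read_pdb_trajectory("traj.pdb")
recs <- profile_trajectory(traj)

format_report(per_base_table(recs, n_frames = 10))
#>   base resid hbond pistack water_bridge hydrophobic total
#> 1 DG11    11     0       0            0          40    40
#> 2 DT24    24     0      60            0           0    60
#> 3 DT25    25     0       0          100           0   100
#> 4 DC26    26    90       0            0           0    90

format_report(per_anchor_table(recs, default_anchors()))
#>   anchor hbond_n hbond_rel water_bridge_n water_bridge_rel total_n total_rel
#> 1      3       9       100              0                0       9     47.37
#> 2   17-β       0         0             10              100      10     52.63

combination_shares(recs, 10)
#> Frame shares by interaction-class combination (10 frames):
#>   hbond+pistack+water_bridge    60.00 %
#>   hbond+water_bridge            30.00 %
#>   water_bridge                  10.00 %
#>   unbound                        0.00 %
#> By cardinality: one 10.00%, two 30.00%, three 60.00%
```

Reading the output: base DC26 forms a hydrogen bond to the ligand's
3-hydroxyl in 9 of 10 frames (90 %), DT24 π-stacks with the ligand ring in
60 % of frames, and every frame carries the water bridge at the 17-β
position — exactly the planted ground truth. The per-anchor table splits
absolute record counts by ligand position; the combination shares label
each frame by the subset of specific interaction classes present
(hydrophobic contacts are non-specific and excluded there).

Secondary-structure annotation of the 35-mer aptamer's pairing
(stem 6–11/31–26, hairpin stem 13–15/22–20):

```r
annotate_sse(rbind(cbind(6:11, 31:26), cbind(13:15, 22:20)), length = 35)
#> SSE annotation over 35 residues, 9 base pairs
#>   5'-end         1-5
#>   stem           6-11, 26-31
#>   interior loop  12, 23-25
#>   hairpin loop   13-22
#>   3'-end         32-35
```

A thin command-line wrapper ships in `inst/cli/aptaprof.R`
(`profile | report | stats | distmap | sse | energy | fixtures`), e.g.

```sh
Rscript inst/cli/aptaprof.R profile --in traj.pdb --out results/
Rscript inst/cli/aptaprof.R report --records results/records.tsv --out results/
```

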