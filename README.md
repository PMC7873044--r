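# cgcontact

Residue-level contact dynamics for coarse-grained trajectories of
multi-domain proteins.

## The problem

Scaffolding proteins such as PICK1 couple a small interaction module (a PDZ
domain) to a large rigid dimeric membrane-binding module (a BAR domain)
through an intrinsically disordered linker, with disordered termini on
either end. Their regulation is dynamic rather than structural: the
tethered domain and the tails visit many positions around the rigid body,
and the biology lives in *which residue pairs touch, how often, and for how
long*. Long coarse-grained (Cα-trace) simulations are the standard way to
observe this, and this package implements the analysis chain such
simulations need:

* **Contacts** — two residues are in contact in a frame when their Cα–Cα
  distance `d ≤ 8 Å`; within one chain the pair must additionally satisfy
  `|i − j| ≥ 5` (inter-chain pairs are always eligible). Per-pair contact
  probability is `100 × n_contact / n_frames` over all pooled trajectory
  frames; maps are displayed as `log10(max(p, floor))`.
* **Lifetimes** — a contact event is a maximal run of consecutive
  in-contact frames within one trajectory; its duration is
  `length × Δ_snapshot / 10⁵` simulation steps (mean ± population SD
  reported; boundary-censored events flagged and included).
* **Geometry** — Kabsch least-squares superposition (SVD with reflection
  exclusion), RMSD series fit on the rigid cores, radius of gyration
  `Rg = √(⟨|r_i − r̄|²⟩)`, anchor-residue distance distributions.
* **Domain positions** — each frame is superposed on the reference body;
  mobile-domain centroids are clustered (seeded k-means, k = 5 by default)
  into preferred positions with per-cluster occupancy fractions that
  partition 100%.

Because published coarse-grained trajectory data is rarely deposited, the
package also contains a **synthetic tethered-domain generator**: a
Metropolis Monte Carlo model of a rigid curved rod (BAR surrogate) with
compact bodies on flexible linkers (PDZ surrogates) and/or flexible tails
(C-terminus surrogates), hard-sphere excluded volume, harmonic virtual
bonds, square-well "sticky" pairs with calibratable contact propensities,
and optional screened-Coulomb charges. Every analysis stage is therefore
testable against planted ground truth and closed-form physics
(freely-jointed-chain statistics, two-state Boltzmann occupancy).

## Worked example

```r
library(cgcontact)

params <- load_preset("system1_like")      # rod + two tethered domains
sys    <- build_system(params)
ens    <- simulate_ensemble(params, n_traj = 2, seed = 42)

top_pairs(ens, sys$topology, "PDZ", "BAR", n = 5)
#>    i name_i  j name_j probability_pct lifetime_mean lifetime_sd n_events
#> 1  5    GLY 47    GLY            5.97       0.01054     0.01094       68
#> 2 36    GLY 61    GLY            5.22       0.00995     0.00922       63
#> 3 37    GLY 65    GLY            4.83       0.00557     0.00524      104
#> 4  4    GLY 51    GLY            4.78       0.00526     0.00469      109
#> 5  4    GLY 47    GLY            4.65       0.00764     0.00850       73
```

The two planted sticky pairs (rod bead 5 with domain bead 47; rod bead 36
with domain bead 61) rank first and second: the analysis recovers the
contacts the generator planted, at single-digit percent probabilities with
lifetimes in units of 10⁵ steps. Flexibility and preferred positions:

```r
rms <- unlist(lapply(ens$trajectories, rmsd_series,
                     topology = sys$topology, reference = sys$coords))
median(rms)
#> 15.2          # Angstrom: large tethered-domain motion, rigid cores fixed

pos <- mobile_positions(ens, sys$topology, "PDZ", "BAR",
                        reference = sys$coords)
cluster_positions(pos, k = 5, seed = 42)
#> cg_clusters: k = 5 ( kmeans , seed 42 )
#>   cluster 1:  26.9%  centroid (59.2, -44.6, -7.5)
#>   cluster 2:  23.1%  centroid (55.8, -39.5, 7.9)
#>   cluster 3:  18.0%  centroid (-52.7, -46.3, -8.2)
#>   cluster 4:  16.8%  centroid (-54.2, -43.3, 9.8)
#>   cluster 5:  15.2%  centroid (-66.7, -36.3, -1.4)
```

The fractions partition 100%; centroids are positions of the mobile domain
in the reference-body frame (Å). Real trajectories enter the same way via
`read_multimodel_pdb()` / `read_coordinate_table()` plus a topology config
(`load_topology()`; see `inst/extdata/pick1_system1_like.yaml` for a
PICK1-like dimer annotation). `run_pipeline()` drives everything from one
YAML config and writes TSV outputs with provenance;
`inst/scripts/cgcontact-pipeline.R` is a shell wrapper around it.

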