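---
title: "Contact dynamics of tethered domains: models, conventions and design choices"
author: "cgcontact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact dynamics of tethered domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgcontact)
```

This vignette is the package's own account of the science it implements:
the contact and lifetime model, the geometric analyses, the clustering
semantics, and — because coarse-grained trajectory data of the systems
this analysis targets is usually not deposited — the synthetic
tethered-domain generator that makes every stage verifiable. It also
records the design decisions that were genuinely open and why they were
resolved the way they were.

## The system picture

The target architecture is a dimeric scaffolding protein of the PICK1
type: a large, rigid, curved dimeric module (a BAR domain, whose concave
face carries a patch of basic residues that binds membranes), one small
tethered interaction module per protomer (a PDZ domain) on an
intrinsically disordered linker, and disordered N-/C-terminal tails. The
interesting biology is auto-regulatory: the tethered domain and the tails
transiently cover or avoid functional surfaces of the rigid body. The
observable is an ensemble of Cα-trace frames from long coarse-grained
simulations, typically several independent trajectories with snapshots
every 10,000 simulation steps.

All analyses operate on the Cα trace only. Residues are addressed by a
single 1-based index concatenated across chains in declaration order, so
an index larger than the first protomer's length denotes the partner
protomer — the convention used by single-running-index contact tables for
dimers. Region labels (`N_TERM`, `PDZ`, `LINKER`, `LINKER_HELIX`, `BAR`,
`C_TERM`, `OTHER`) partition the residue list and are supplied by a YAML
config, because exact boundaries are construct-specific and rarely
printed; the shipped PICK1-like configs are explicitly labelled as
plausible fixtures, not literature facts.

## Contacts, probabilities, lifetimes

A residue pair is in contact in a frame when its Cα–Cα distance is at
most `cutoff` (default 8 Å — the boundary itself counts, "8 Å or less").
Within a chain the pair must satisfy `|local_i − local_j| ≥ 5` (default);
this excludes trivial sequence neighbours. Two readings were open here:

* whether "at least five apart" means `≥ 5` or `> 5` — `≥ 5` is
  implemented and the threshold is a plain parameter;
* whether the separation rule applies across chains — it does not:
  inter-protomer pairs have no meaningful sequence separation, and
  reported inter-protomer pairs would otherwise depend on an arbitrary
  concatenated-index gap. Inter-chain pairs are always eligible.

Contact probability is `100 × (frames in contact) / (total frames)` over
all trajectories pooled with equal weight per frame, so longer
trajectories weight proportionally. Contact maps hold these percentages;
for display the conventional transform is `log10(max(p, floor))` with a
default floor of 0.01% so that empty cells remain representable on a log
colour scale (the floor is explicit and configurable).

A **contact event** is a maximal run of consecutive in-contact frames
within one trajectory; runs never span trajectory boundaries. Lifetime =
`length_frames × snapshot_interval / 10⁵ steps`, the conventional unit
for such tables. Two conventions had to be fixed:

* **Censoring.** An event touching its trajectory's first or last frame
  has only a partially observed duration. Excluding such events would
  bias systematically *against* long-lived contacts, so they are included
  in the statistics and flagged, letting users re-filter.
* **Dispersion.** The reported `mean ± sd` is descriptive, so the SD is
  the population SD (divide by *n*); `sd_type = "sample"` switches to the
  n−1 estimator.

Ranked pair tables sort by probability (descending), breaking ties by
lifetime mean (descending), then by index — a deterministic total order.
Interaction types are classified from residue identities alone:
`ELECTROSTATIC` for opposite charges, `HYDROPHOBIC` when both residues
are apolar, `POLAR` when both are polar, otherwise `MIXED`. The default
table counts Tyr, Cys, Gly and Pro as hydrophobic and His as positive;
this reproduces the conventional labelling of Tyr/Cys-containing pairs as
hydrophobic and Lys–Asp pairs as electrostatic, and is overridable per
config. No energetic decomposition is attempted — the classification is a
narrative aid, as in the tables it mirrors.

## Geometry

Superposition is the Kabsch least-squares solution via SVD of the 3×3
cross-covariance, with the determinant-sign correction that excludes
reflections; a near-zero second singular value (collinear selection)
raises a conditioning error rather than returning a garbage rotation.
RMSD series fit each frame on the topology's *restrained regions* (the
rigid cores — the regions a simulation would hold together with
restraints) and report RMSD over all residues: fitting on flexible parts
would absorb exactly the motion being measured. Both selections are
arguments. The reference defaults to the initial structure, matching the
"deviation from the start" reading of such plots.

Radius of gyration uses uniform bead masses (a Cα trace carries no useful
mass weighting). Anchor distances are single Cα–Cα distances per frame —
the caption-level definition of domain-to-rod distance plots; a
region-centroid mode is provided because prose descriptions of the same
analyses sometimes say "centroid distance". Distributions report
frequency = proportion of frames per bin, with 50 equal-width bins over
the observed range by default, plus the sample median and range.

## Mobile-domain position clustering

Each frame is superposed onto a reference structure by its reference-body
Cα sites; the centroid of each copy of the mobile region (copies =
chains, so the two tethered domains of a dimer are separate observation
streams pooled into one set) is one observation. Observations are
clustered with seeded k-means, `k = 5` by default — the conventional
number of "most probable positions" reported for such systems — with
clusters relabelled in descending occupancy order.

Partition semantics are enforced deliberately: every observation belongs
to exactly one cluster and the fractions sum to 100%. Published cluster
percentages for tail positions sometimes sum to well over 100%
(overlapping membership or per-copy accounting that is never specified);
a partitional method with recorded algorithm, parameters and seed is the
minimal faithful, reproducible choice, and this implementation makes no
attempt to reproduce over-100% totals. `occupancy_report()` interprets
clusters against a named special set (e.g. the basic membrane-binding
patch): a centroid within 12 Å (the 8 Å contact cutoff plus 4 Å of slack
for the domain-radius offset between a centroid and its surface residues)
is flagged as covering the set.

## The synthetic generator

The generator emulates the architecture, not the chemistry: a rigid rod
of `B` beads on a circular arc (chord spacing = bond length 3.8 Å, radius
of curvature 60 Å by default), compact rigid bodies (lattice clusters at
≥ hard-core spacing) tethered by flexible linkers, and flexible tails.
The energy, in kT units, is

* harmonic virtual bonds `k (r − b)²` with `k = 100 kT/Å²` (thermal bond
  SD ≈ 0.07 Å — effectively stiff),
* hard-sphere exclusion (bead radius 2 Å) between non-bonded beads of
  different rigid units,
* square wells of depth ε and width 8 Å on declared sticky pairs — width
  matched to the contact cutoff so that "in the well" and "in contact"
  coincide,
* optional screened Coulomb `λ_B q_i q_j e^{−r/λ_D}/r` with Bjerrum
  length 7 Å and Debye length 10 Å (aqueous, physiological-ish salt).

Sampling is Metropolis Monte Carlo, not dynamics, because every analysis
the package performs consumes equilibrium-ensemble quantities (contact
probabilities, positional distributions) and MC provides exact-seed
reproducibility cheaply. Lifetimes measured on MC trajectories are in
recorded-frame pseudo-time: they exercise the lifetime *estimator*, and no
attempt is made to mimic physical kinetics or absolute lifetimes. The
move set is single-bead Gaussian displacements on flexible beads, pivot
rotations of chain subtrees (a tail tip, or a linker segment carrying its
rigid body), and rigid-body translations/rotations of mobile bodies — all
proposals are symmetric, so plain Metropolis acceptance targets the
Boltzmann distribution exactly; the pivot moves exist purely to
decorrelate chain conformations quickly. Simulation temperature in the
emulated studies (e.g. 350 K) is metadata: energies here are in kT and a
dimensionless temperature factor scales the acceptance test.

Randomness follows one contract: a root seed, with per-trajectory streams
derived deterministically from the trajectory index and the calibration
stream offset by a fixed constant, so production and calibration runs are
independent but individually reproducible.

**Ground truth.** `calibrate_ground_truth()` measures each sticky pair's
contact probability on an independent, longer run, with binomial standard
errors, and checks monotonicity of probability in ε across a grid. Two
closed-form references validate the sampler itself: a single particle in
a hard sphere with a square well, whose occupancy is exactly
`e^ε V_in / (e^ε V_in + V_out)`, and a free chain without excluded
volume, whose end-to-end distance must match direct freely-jointed-chain
sampling (the bond-length SD of 0.07 Å is negligible at the comparison's
resolution).

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: real force-field energetics, side-chain
interaction sites, solvent or membrane, realistic kinetics, and
sequence-specific interactions beyond the planted wells and charges. The
generator demonstrates that the *analysis* is correct, not that any
particular biological conclusion is.

## Numerical choices and degenerate inputs

* Distance boundary: `d ≤ cutoff` exactly; a pair at 8.000 Å is a
  contact, at 8.001 Å is not.
* k-means: seeded, `nstart = 10`, relabelled by occupancy; `k = n`
  degenerates to one observation per cluster; `k > n` is an error.
* Kabsch: conditioning error when the second singular value falls below
  `1e-8` of the first (collinear selections).
* Empty event lists make lifetime statistics an error, not NaN; empty
  top-pair tables are a valid result, not an error.
* Bond-envelope validation uses a 6σ band: a Boltzmann-distributed bond
  exceeds 3σ with probability ≈ 0.3% per sample, so over thousands of
  bond-frame samples a 3σ check would fail by design; 6σ has violation
  odds ~10⁻⁹ per sample.
* Planted-contact binding in the tethered-domain presets is a rare-event
  process: the spread of a time-fraction estimate is governed by the
  number of binding events, not frames, so equality checks between
  symmetric pairs use `se ≈ p·√(2/n_events)` rather than the naive
  binomial error. The fast-mixing two-state toy is used where binomial
  errors are the right scale.

## Problem sizes

The shipped presets run 6×10⁵ MC steps per trajectory with frames every
300 steps (2,000 frames), two to four trajectories per ensemble;
calibration runs are twice as long with an independent seed stream. The
closed-form checks use 2,000–5,000 recorded frames against 20,000 direct
reference samples. These sizes put Monte-Carlo errors comfortably below
the effects being demonstrated (planted probabilities of 5–20%, two-state
occupancy errors under 1%) while keeping a full test run around a minute;
they are package defaults, and every one of them is a plain parameter.

## Known limitations

* Contact analysis is Cα-only by design; side-chain-center definitions
  would change absolute probabilities.
* Lifetime statistics include censored events; for trajectories much
  shorter than typical contact lifetimes the censoring bias correction is
  the user's responsibility (the flag is exported).
* The clustering is positional, not conformational: it answers "where is
  the domain", not "what shape is the complex".
* `bio3d` handles PDB I/O; exotic PDB dialects inherit its behaviour.
  Binary trajectory formats (DCD/XTC) are out of scope — convert to
  multi-model PDB or the tabular format upstream.
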