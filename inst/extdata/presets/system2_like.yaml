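# Rod + two flexible charged tails (dimeric reference body with C-terminus
# surrogates). Bead layout: rod 1-40 (chain A), tail 41-60 (chain B,
# attached at rod bead 1), tail 61-80 (chain C, attached at rod bead 40).
# Rod beads 18-22 carry +1 charges (basic-patch surrogate, named LYS);
# the last five beads of each tail carry -1 (acidic-stretch surrogate,
# named ASP). Two sticky pairs plant hydrophobic-style contacts near the
# attachment sites.
ref_body: {n_beads: 40, radius_of_curvature: 60}
mobile_bodies: []
linkers: []
tails: [20, 20]
sticky_pairs:
  - {i: 6, j: 50, eps: 2.0, width: 8.0}
  - {i: 35, j: 70, eps: 2.0, width: 8.0}
charges:
  - {index: 18, q: 1}
  - {index: 19, q: 1}
  - {index: 20, q: 1}
  - {index: 21, q: 1}
  - {index: 22, q: 1}
  - {index: 56, q: -1}
  - {index: 57, q: -1}
  - {index: 58, q: -1}
  - {index: 59, q: -1}
  - {index: 60, q: -1}
  - {index: 76, q: -1}
  - {index: 77, q: -1}
  - {index: 78, q: -1}
  - {index: 79, q: -1}
  - {index: 80, q: -1}
n_steps: 600000
record_interval: 300
n_equil: 30000
seed: 1
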