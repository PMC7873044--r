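# Rod + two mobile compact bodies on flexible linkers (dimeric reference
# body with two tethered-domain surrogates). Bead layout (see bead_layout):
# rod 1-40 (chain A), linker 41-46 + body 47-54 (chain B, attached at rod
# bead 1), linker 55-60 + body 61-68 (chain C, attached at rod bead 40).
# Two symmetric sticky pairs plant preferred domain positions on the rod.
ref_body: {n_beads: 40, radius_of_curvature: 60}
mobile_bodies: [8, 8]
linkers: [6, 6]
tails: []
sticky_pairs:
  - {i: 5, j: 47, eps: 3.0, width: 8.0}
  - {i: 36, j: 61, eps: 3.0, width: 8.0}
n_steps: 600000
record_interval: 300
n_equil: 30000
seed: 1
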