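# Minimal calibration case: 6-bead rod (chain A) with a 4-bead tail
# (beads 7-10, chain B, attached at rod bead 1) and a single sticky pair
# between rod bead 4 and the tail tip. Used for ground-truth calibration
# and planted-contact recovery checks.
ref_body: {n_beads: 6, radius_of_curvature: 60}
mobile_bodies: []
linkers: []
tails: [4]
sticky_pairs:
  - {i: 4, j: 10, eps: 2.0, width: 8.0}
n_steps: 600000
record_interval: 300
n_equil: 20000
seed: 1
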