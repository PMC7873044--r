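# Synthetic PICK1-like dimer topology, system-1 flavour (PDZ + linker + BAR).
# Region boundaries and the 360-residue protomer length are plausible
# FIXTURE values chosen for testing, not experimentally determined facts:
# published residue tables for this system never print the protomer length,
# so the offset of second-protomer indices (e.g. 608 -> chain B, 248) is an
# inference documented here. Residue names are GLY except the handful of
# positions exercised by tests (e.g. V50, L114, S130, the K251..K268 basic
# patch, anchors L60/S130/T167/S262 and D390 = chain B residue 30).
chains:
  - id: A
    residues: GGGGGGGGGGGGGGGGGGGGGGGGGGGGGDGGGGGGGGGGAQYCGGGGGVGGGDGGGGGLGGGGGAGGGGGGGGGGGGGGGGGVGGGGGGGGGGGGGGGGGGGGGGGGGGGMSLGGVLGGGGGGGGGGGSGGGGGGGGGGGGGGGGGGGGGRLGGLGGGAGGGGGGTGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGSGGKKGGGGKFGGGSGGLKGKGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
  - id: B
    residues: GGGGGGGGGGGGGGGGGGGGGGGGGGGGGDGGGGGGGGGGAQYCGGGGGVGGGDGGGGGLGGGGGAGGGGGGGGGGGGGGGGGVGGGGGGGGGGGGGGGGGGGGGGGGGGGMSLGGVLGGGGGGGGGGGSGGGGGGGGGGGGGGGGGGGGGRLGGLGGGAGGGGGGTGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGSGGKKGGGGKFGGGSGGLKGKGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
regions:
  - {label: N_TERM, start: 1, end: 21}
  - {label: PDZ, start: 22, end: 105}
  - {label: LINKER, start: 106, end: 107}
  - {label: LINKER_HELIX, start: 108, end: 126}
  - {label: LINKER, start: 127, end: 135}
  - {label: BAR, start: 136, end: 360}
special_sets:
  basic_patch: {local: [251, 252, 257, 266, 268]}
  anchors: {concatenated: [60, 130, 167, 262, 390]}
restrained_regions: [PDZ, BAR]
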