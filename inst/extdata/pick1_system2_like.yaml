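# Synthetic PICK1-like dimer topology, system-2 flavour (BAR + C-terminus).
# FIXTURE boundaries (BAR 1-344, C-terminus 345-404 per protomer): chosen so
# that the residue numbering of published BAR/C-terminus contact tables
# (A206, K209, M341, S342 on the BAR side; Y345, D347, C348 on the
# C-terminal side; acidic stretch D380-D389; basic patch K251..K268) is
# internally consistent. Not experimentally determined values.
chains:
  - id: A
    residues: GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGAGGKFGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGKKGGGGKGGGGGGGGKGKGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGTMSGGYGDCYGVGGGGGGGGGGGGGGGGGGGGGGGGGGGGDDDDDDDDDDGGGGGGGGGGGGGGG
  - id: B
    residues: GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGAGGKFGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGKKGGGGKGGGGGGGGKGKGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGTMSGGYGDCYGVGGGGGGGGGGGGGGGGGGGGGGGGGGGGDDDDDDDDDDGGGGGGGGGGGGGGG
regions:
  - {label: BAR, start: 1, end: 344}
  - {label: C_TERM, start: 345, end: 404}
special_sets:
  basic_patch: {local: [251, 252, 257, 266, 268]}
  acidic_stretch: {local: [380, 381, 382, 383, 384, 385, 386, 387, 388, 389]}
restrained_regions: [BAR]
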