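# Xenon contact-site clusters on the tagged Y2 receptor and on bound NPY:
# per site, the three residues most often subjected to xenon contact.
apo:
  NTER:
    segment: receptor
    residues: [L40, I41, K45]
  ECL1:
    segment: receptor
    residues: [L112, M113, G114]
  ECL2_1:
    segment: receptor
    residues: [I195, P196, F198]
  ECL2_2:
    segment: receptor
    residues: [W207, P208, G209]
  ECL3:
    segment: receptor
    residues: [Q296, D299, L300]
npy:
  NTER:
    segment: receptor
    residues: [L40, I41, S43]
  ECL2_1:
    segment: receptor
    residues: [I195, P196, F198]
  ECL3:
    segment: receptor
    residues: [L300, K301, E302]
  NPY_NTER:
    segment: ligand
    residues: [G9, E10, A12]
  NPY_helix:
    segment: ligand
    residues: [A14, M17, Y21]
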