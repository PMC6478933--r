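# Species / charge / radius rules for poreclog's synthetic fixtures.
# Radii and charges here are the synthetic generator's own round values,
# not force-field parameters.
species:
  WATER:
    residues: [HOH, TIP3, SOL, WAT]
    atoms: [OW]
  ION_K:
    residues: [POT]
    atoms: [K, POT]
  ION_CL:
    residues: [CLA]
    atoms: [CL, CLA]
  PORE:
    residues: [WAL]
    atoms: [WAL]
  PEPTIDE:
    residues: [BED]
    atoms: [BED]
charges:
  by_atom: {}
  by_species:
    WATER: 0.0
    ION_K: 1.0
    ION_CL: -1.0
    PORE: 0.0
    PEPTIDE: 0.0
    OTHER: 0.0
radii:
  by_atom:
    OW: 1.4
    K: 1.5
    CL: 1.8
    WAL: 1.5
    BED: 2.0
  by_element: {}
masses:
  by_atom:
    OW: 18.0
    K: 39.1
    CL: 35.45
    WAL: 100.0
    BED: 100.0
  default: 1.0
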