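# Generic CHARMM-flavoured species rules for real nanopore systems.
# Radii: element-based Bondi-style values (the occupancy definition needs a
# declared radius set; override by_atom for force-field-specific radii).
# Charges for protein/lipid atoms must come from a user-supplied by_atom
# table (e.g. extracted from a PSF); only rigid defaults for water and the
# monovalent ions are shipped.
species:
  WATER:
    residues: [TIP3, TIP4, SPC, SPCE, HOH, SOL, WAT]
  ION_K:
    residues: [POT]
    atoms: [POT, "K+"]
  ION_CL:
    residues: [CLA]
    atoms: [CLA, "CL-"]
  LIPID:
    residues: [POPC, POPE, POPS, DPPC, DOPC, DMPC]
charges:
  by_atom:
    OH2: -0.834
    H1: 0.417
    H2: 0.417
    POT: 1.0
    CLA: -1.0
  by_species: {}
radii:
  by_atom:
    POT: 1.76
    CLA: 1.81
  by_element:
    H: 1.2
    C: 1.7
    N: 1.55
    O: 1.52
    S: 1.8
    P: 1.8
    K: 1.76
    CL: 1.81
    NA: 1.36
masses:
  by_atom: {}
  default: 12.0
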