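[
  {
    "name": "roGFP1", "kind": "redox",
    "R_A": 1.0, "R_B": 6.1, "delta2": 0.25,
    "e0_mv": -288, "z": 2, "temperature_K": 298.15,
    "note": "Midpoint potential from the primary roGFP literature (Hanson et al. 2004, J Biol Chem). Ratio endpoints normalized (R_A = 1); dynamic range and delta2 reconstructed representative values for 400/480 nm dual-excitation imaging, not an instrument calibration."
  },
  {
    "name": "roGFP2", "kind": "redox",
    "R_A": 1.0, "R_B": 5.9, "delta2": 0.30,
    "e0_mv": -272, "z": 2, "temperature_K": 298.15,
    "note": "Midpoint from Hanson et al. 2004. Reconstructed representative conversion factors."
  },
  {
    "name": "roGFP3", "kind": "redox",
    "R_A": 1.0, "R_B": 1.9, "delta2": 0.55,
    "e0_mv": -299, "z": 2, "temperature_K": 298.15,
    "note": "Midpoint from Hanson et al. 2004; low dynamic range variant. Reconstructed representative conversion factors."
  },
  {
    "name": "roGFP4", "kind": "redox",
    "R_A": 1.0, "R_B": 2.3, "delta2": 0.55,
    "e0_mv": -286, "z": 2, "temperature_K": 298.15,
    "note": "Midpoint from Hanson et al. 2004; low dynamic range variant. Reconstructed representative conversion factors."
  },
  {
    "name": "roGFP5", "kind": "redox",
    "R_A": 1.0, "R_B": 5.4, "delta2": 0.30,
    "e0_mv": -296, "z": 2, "temperature_K": 298.15,
    "note": "Midpoint from the Remington-lab roGFP series; carries two additional cysteines. Reconstructed representative conversion factors."
  },
  {
    "name": "roGFP6", "kind": "redox",
    "R_A": 1.0, "R_B": 3.3, "delta2": 0.40,
    "e0_mv": -280, "z": 2, "temperature_K": 298.15,
    "note": "Midpoint from the Remington-lab roGFP series. Reconstructed representative conversion factors."
  },
  {
    "name": "roGFP1-R9", "kind": "redox",
    "R_A": 1.0, "R_B": 4.3, "delta2": 0.25,
    "e0_mv": -263, "z": 2, "temperature_K": 298.15,
    "note": "Midpoint from Cannon & Remington 2006 (roGFP1 R9 substitution variant). Reconstructed representative conversion factors."
  },
  {
    "name": "roGFP1-R12", "kind": "redox",
    "R_A": 1.0, "R_B": 7.8, "delta2": 0.171,
    "e0_mv": -265, "z": 2, "temperature_K": 298.15,
    "note": "Midpoint from Cannon & Remington 2006. Overall dynamic range 7.8 as reported in vivo in C. elegans pharyngeal muscle (in vitro 5.0); ratio endpoints normalized; delta2 reconstructed. Because all predictions depend on (R_A, R_B) only through their ratio, the normalization is without loss."
  },
  {
    "name": "roGFP1-iL", "kind": "redox",
    "R_A": 1.0, "R_B": 2.0, "delta2": 0.45,
    "e0_mv": -246, "z": 2, "temperature_K": 298.15,
    "note": "Insertion variant with raised midpoint (Lohman & Remington 2008). Reconstructed representative conversion factors."
  },
  {
    "name": "roGFP1-iE", "kind": "redox",
    "R_A": 1.0, "R_B": 1.8, "delta2": 0.45,
    "e0_mv": -236, "z": 2, "temperature_K": 298.15,
    "note": "Insertion variant designed for more oxidizing compartments (Lohman & Remington 2008). Reconstructed representative conversion factors."
  },
  {
    "name": "roGFP2-iL", "kind": "redox",
    "R_A": 1.0, "R_B": 3.6, "delta2": 0.35,
    "e0_mv": -241, "z": 2, "temperature_K": 298.15,
    "note": "Insertion variant with raised midpoint and higher dynamic range than roGFP1-iE. Reconstructed representative conversion factors."
  },
  {
    "name": "pHluorin-ratiometric", "kind": "pH",
    "R_A": 3.0, "R_B": 0.6, "delta2": 2.5,
    "pKa": 7.1,
    "note": "Dual-excitation green-fluorescent pH sensor (Miesenboeck et al. 1998); R decreases upon deprotonation (R_B < R_A). Reconstructed representative conversion factors."
  },
  {
    "name": "pHRed", "kind": "pH",
    "R_A": 1.0, "R_B": 3.0, "delta2": 0.6,
    "pKa": 6.6,
    "note": "Dual-excitation red-fluorescent pH sensor (Tantama et al. 2011). Reconstructed representative conversion factors."
  },
  {
    "name": "E2GFP-dual-excitation", "kind": "pH",
    "R_A": 1.0, "R_B": 4.0, "delta2": 0.5,
    "pKa": 6.9,
    "note": "E2GFP used in dual-excitation green-fluorescence modality (Bizzarri et al. 2006). Reconstructed representative conversion factors."
  },
  {
    "name": "E2GFP-dual-emission", "kind": "pH",
    "R_A": 1.0, "R_B": 2.2, "delta2": 0.9,
    "pKa": 6.9,
    "note": "Same protein as E2GFP-dual-excitation in single-excitation dual-emission modality; the two modalities differ in overall and second-band dynamic range, hence in predicted accuracy. Reconstructed representative conversion factors."
  },
  {
    "name": "Frex", "kind": "ligand",
    "R_A": 1.0, "R_B": 8.0, "delta2": 0.9,
    "pKd": 5.4,
    "note": "NADH sensor (Zhao et al. 2011); Kd about 4 uM. Reconstructed representative conversion factors; higher dynamic range than FrexH."
  },
  {
    "name": "FrexH", "kind": "ligand",
    "R_A": 1.0, "R_B": 3.0, "delta2": 0.9,
    "pKd": 7.4,
    "note": "High-affinity NADH sensor (Zhao et al. 2011); Kd about 40 nM. Reconstructed representative conversion factors."
  },
  {
    "name": "iNAP1", "kind": "ligand",
    "R_A": 1.0, "R_B": 9.0, "delta2": 0.5,
    "pKd": 5.7,
    "note": "NADPH sensor (Tao et al. 2017); Kd about 2 uM. Reconstructed representative conversion factors."
  },
  {
    "name": "iNAP1-mCherry", "kind": "ligand",
    "R_A": 1.0, "R_B": 3.5, "delta2": 1.0,
    "pKd": 5.7,
    "note": "pH-resistant fusion that normalizes iNAP1 by mCherry fluorescence, sacrificing dynamic range in one band and hence accuracy. Reconstructed representative conversion factors."
  },
  {
    "name": "FHisJ", "kind": "ligand",
    "R_A": 1.0, "R_B": 4.0, "delta2": 0.7,
    "pKd": 4.8,
    "note": "FRET-free histidine sensor (Hu et al. 2017); Kd in the tens of micromolar. Reconstructed representative conversion factors."
  }
]
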