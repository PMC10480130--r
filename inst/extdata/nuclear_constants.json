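{
  "version": "1.0.0",
  "comment": "Embedded nuclear and physical constants; see README.md in this directory for provenance.",
  "physical": {
    "amu_MeV": 931.49410242,
    "amu_kg": 1.66053906660e-27,
    "electron_mass_u": 5.48579909065e-4,
    "avogadro": 6.02214076e23,
    "elementary_charge_C": 1.602176634e-19,
    "epsilon0_F_per_m": 8.8541878128e-12,
    "MeV_per_J": 6.241509074e12,
    "J_per_MeV": 1.602176634e-13,
    "boltzmann_eV_per_K": 8.617333262e-5
  },
  "nuclides": {
    "n":    {"Z": 0, "A": 1,  "mass_u": 1.00866491595},
    "H-1":  {"Z": 1, "A": 1,  "mass_u": 1.00782503224},
    "H-2":  {"Z": 1, "A": 2,  "mass_u": 2.01410177812},
    "H-3":  {"Z": 1, "A": 3,  "mass_u": 3.01604928199},
    "He-3": {"Z": 2, "A": 3,  "mass_u": 3.01602932008},
    "He-4": {"Z": 2, "A": 4,  "mass_u": 4.00260325413},
    "Li-7": {"Z": 3, "A": 7,  "mass_u": 7.01600343666},
    "B-10": {"Z": 5, "A": 10, "mass_u": 10.01293695},
    "B-11": {"Z": 5, "A": 11, "mass_u": 11.00930536},
    "C-12": {"Z": 6, "A": 12, "mass_u": 12.0},
    "C-14": {"Z": 6, "A": 14, "mass_u": 14.003241988},
    "N-14": {"Z": 7, "A": 14, "mass_u": 14.00307400443},
    "O-16": {"Z": 8, "A": 16, "mass_u": 15.99491461957}
  },
  "excited_levels_MeV": {
    "Li-7": 0.47761
  },
  "b10_capture": {
    "branching_excited": 0.939,
    "branching_ground": 0.061
  },
  "cross_sections": {
    "E_ref_eV": 0.025,
    "capture_thermal_barns": {
      "B-10": 3837.0,
      "H-1": 0.332,
      "N-14": 1.83,
      "O-16": 0.0
    },
    "capture_kind": {
      "B-10": "B10_nalpha",
      "H-1": "H_ngamma",
      "N-14": "N14_np",
      "O-16": "negligible"
    },
    "elastic_barns": {
      "H-1": 20.4,
      "C-12": 4.7,
      "N-14": 10.0,
      "O-16": 3.8,
      "B-10": 0.0
    }
  },
  "tissue": {
    "name": "ICRU four-component soft tissue",
    "density_g_cm3": 1.0,
    "mass_fractions": {
      "H-1": 0.101,
      "C-12": 0.111,
      "N-14": 0.026,
      "O-16": 0.762
    }
  },
  "gamma_attenuation_per_cm": {
    "0.478": 0.0967,
    "2.224": 0.0455
  }
}
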