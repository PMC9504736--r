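{
  "_comment": "Published structural characterization and ligand-profiling values for the JAK1 (PDB 6N7A, pocket 865-1154) and JAK2 (PDB 4YTH, pocket 842-1130) kinase-domain binding grottoes, with the comparison tolerances used by compare_report(). Docking affinities (kcal/mol) are included for context only and excluded from pass/fail: no docking is performed by this package.",
  "jak1": {
    "n_residues": {"value": 290, "tolerance": 0},
    "sasa_total": {"value": 29255.336, "tolerance": "5%"},
    "hb_count": {"value": 189, "tolerance": "10%"},
    "nonpolar_pct": {"value": 36.8, "tolerance": 0.5},
    "polar_pct": {"value": 30.9, "tolerance": 0.5},
    "charged_pct": {"value": 31.6, "tolerance": 0.5},
    "n_helices": {"value": 17},
    "n_strands": {"value": 13},
    "n_cross": {"value": 310, "tolerance": "15%"},
    "n_inside": {"value": 43, "tolerance": "15%"},
    "cross_mean": {"value": 8.28, "tolerance": 0.3},
    "cross_sd": {"value": 1.37},
    "inside_mean": {"value": 7.80},
    "inside_sd": {"value": 1.54}
  },
  "jak2": {
    "n_residues": {"value": 289, "tolerance": 0},
    "sasa_total": {"value": 31252.359, "tolerance": "5%"},
    "hb_count": {"value": 198, "tolerance": "10%"},
    "nonpolar_pct": {"value": 38.4, "tolerance": 0.5},
    "polar_pct": {"value": 30.4, "tolerance": 0.5},
    "charged_pct": {"value": 30.4, "tolerance": 0.5},
    "n_helices": {"value": 17},
    "n_strands": {"value": 12},
    "n_cross": {"value": 333, "tolerance": "15%"},
    "n_inside": {"value": 38, "tolerance": "15%"},
    "cross_mean": {"value": 8.25, "tolerance": 0.3},
    "cross_sd": {"value": 1.40},
    "inside_mean": {"value": 7.67},
    "inside_sd": {"value": 1.62}
  },
  "contact_distance_modes": {"lower": [7.7, 7.8], "upper": 8.3},
  "pocket_identity_percent": {"value": 54, "tolerance": 3},
  "ligands": {
    "jak1": {
      "locus": ["ARG879", "LEU881", "GLY884", "GLY962"],
      "decernotinib": {"affinity": {"value": -8.7, "excluded": true},
                       "n_hb": {"value": 1},
                       "n_hydrophobic": {"value": 10, "tolerance": 2}},
      "KEV": {"affinity": {"value": -8.7, "excluded": true},
              "n_hb": {"value": 1},
              "n_hydrophobic": {"value": 15, "tolerance": 2}},
      "ruxolitinib": {"affinity": {"value": -8.3, "excluded": true},
                      "n_hb": {"value": 0, "tolerance": 0},
                      "n_hydrophobic": {"value": 16, "tolerance": 2}}
    },
    "jak2": {
      "locus": ["LEU855", "GLY858", "ARG980", "LEU983"],
      "decernotinib": {"affinity": {"value": -8.7, "excluded": true},
                       "n_hb": {"value": 0},
                       "n_hydrophobic": {"value": 13, "tolerance": 2}},
      "KEV": {"affinity": {"value": -8.6, "excluded": true},
              "n_hb": {"value": 1},
              "n_hydrophobic": {"value": 12, "tolerance": 2}},
      "ruxolitinib": {"affinity": {"value": -8.0, "excluded": true},
                      "n_hb": {"value": 0, "tolerance": 0},
                      "n_hydrophobic": {"value": 11, "tolerance": 2}}
    }
  }
}
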