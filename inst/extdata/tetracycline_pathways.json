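{
  "parent": "tetracycline",
  "parent_mz": 445.1592,
  "parent_rt_min": 6.68,
  "bde": {
    "comment": "DFT (PBE/L1) C-H bond dissociation energies of tetracycline by carbon position: total energy change dE and Gibbs energy change dG for TC -> Radical(Cn). + H., kcal/mol.",
    "positions": ["C4", "C5", "C6", "C9", "C14", "C15", "C19"],
    "dE_kcal_mol": [113.5, 115.2, 115.5, 77.5, 94.7, 99.7, 74.8],
    "dG_kcal_mol": [105.4, 105.8, 106.6, 69.4, 85.2, 90.9, 66.8]
  },
  "energy_notes": {
    "dG_C5_minus_C19_kcal_mol": 39.0,
    "dE_C5_minus_C19_kcal_mol": 40.4,
    "dp460_isomer_C19_vs_C5_penalty_kcal_mol": 6.3,
    "comment": "The C19 hydrogen is the most weakly bound on both the dE and dG scales; the hydroxylated-product isomer with OH at C19 lies 6.3 kcal/mol above the C5 isomer, so C-H cleavage (not OH placement) selects the observed product."
  },
  "pathways": [
    {
      "product": "DP-TC-460",
      "mz": 461.1549,
      "table_dose_kGy": 1,
      "text_dose_kGy": 1,
      "fitted_D0_kGy": 0.98,
      "uncertain": false,
      "net_energy_kcal_mol": null,
      "steps": [
        {"reaction": "H-elimination", "site": "C19", "dE_kcal_mol": 74.8,
         "direct": 1, "indirect": 0,
         "note": "direct ionization breaks the weakest C-H bond"},
        {"reaction": "hydroxylation", "site": "C19", "dE_kcal_mol": null,
         "direct": 0, "indirect": 1,
         "note": "radiolytic OH. adds to the primary radical"}
      ]
    },
    {
      "product": "DP-TC-399",
      "mz": 400.1024,
      "table_dose_kGy": 1,
      "text_dose_kGy": 1,
      "fitted_D0_kGy": 0.09,
      "uncertain": false,
      "net_energy_kcal_mol": null,
      "steps": [
        {"reaction": "deaminomethylation", "site": "C19", "dE_kcal_mol": 38.4,
         "direct": 1, "indirect": 0,
         "note": "dimethylamine group breaks off C19"},
        {"reaction": "H-elimination", "site": null, "dE_kcal_mol": 37.8,
         "direct": 1, "indirect": 0,
         "note": "hydrogen radical dissociates"}
      ]
    },
    {
      "product": "DP-TC-383",
      "mz": 384.1074,
      "table_dose_kGy": 1,
      "text_dose_kGy": 1,
      "fitted_D0_kGy": 0.09,
      "uncertain": true,
      "net_energy_kcal_mol": -72.8,
      "steps": [
        {"reaction": "dehydroxylation", "site": "C18", "dE_kcal_mol": null,
         "direct": 1, "indirect": 0,
         "note": "hydroxyl group eliminated from the DP-TC-399 skeleton"},
        {"reaction": "H-addition", "site": "C18", "dE_kcal_mol": null,
         "direct": 0, "indirect": 1,
         "note": "radiolytic H. caps the site"},
        {"reaction": "deaminomethylation", "site": "C19", "dE_kcal_mol": null,
         "direct": 1, "indirect": 0},
        {"reaction": "H-elimination", "site": "C14", "dE_kcal_mol": null,
         "direct": 1, "indirect": 0}
      ]
    },
    {
      "product": "DP-TC-415",
      "mz": 416.1334,
      "table_dose_kGy": 1,
      "text_dose_kGy": 3,
      "fitted_D0_kGy": 0.53,
      "uncertain": false,
      "net_energy_kcal_mol": -22.2,
      "steps": [
        {"reaction": "methyl-elimination", "site": "N(CH3)2", "dE_kcal_mol": null,
         "direct": 1, "indirect": 0,
         "note": "methyl radical leaves the dimethylamino nitrogen"},
        {"reaction": "amination", "site": "C22", "dE_kcal_mol": null,
         "direct": 2, "indirect": 1,
         "note": "loss of the amino group from C22; the source narrative counts three direct events plus one indirect H. ionization for the whole pathway without stating the split across steps"}
      ]
    },
    {
      "product": "DP-TC-436",
      "mz": 437.1205,
      "table_dose_kGy": 3,
      "text_dose_kGy": 3,
      "fitted_D0_kGy": 1.04,
      "uncertain": false,
      "net_energy_kcal_mol": -68.3,
      "steps": [
        {"reaction": "hydroxylation", "site": "C8", "dE_kcal_mol": null,
         "direct": 0, "indirect": 1},
        {"reaction": "hydroxylation", "site": "C9", "dE_kcal_mol": null,
         "direct": 0, "indirect": 1},
        {"reaction": "deaminomethylation", "site": "C19", "dE_kcal_mol": null,
         "direct": 1, "indirect": 0},
        {"reaction": "amination", "site": "C19", "dE_kcal_mol": null,
         "direct": 0, "indirect": 1,
         "note": "NH2. radical adds where the dimethylamino group left"},
        {"reaction": "methyl-elimination", "site": "C10", "dE_kcal_mol": null,
         "direct": 1, "indirect": 0}
      ]
    }
  ]
}
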