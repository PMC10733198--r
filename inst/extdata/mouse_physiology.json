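{
  "species": "mouse_default",
  "comment": "Curated healthy-mouse CNS physiology. literature_values are the collected source values; aggregation is how the final value was produced (mean, median, single = adopted as printed, derived = computed from other parameters on load). Units are reporting units; the loader canonicalizes to ml / ml/min / cm / cm2.",
  "parameters": [
    {"name": "V_brain_total", "unit": "ul", "aggregation": "median",
     "literature_values": [303, 360, 495, 150, 350, 360, 360],
     "source_refs": ["lit"]},
    {"name": "V_ECF", "unit": "ul", "aggregation": "single",
     "literature_values": [67], "final_value": 67},
    {"name": "V_ICF", "unit": "ul", "aggregation": "derived",
     "literature_values": [], "derivation": "0.8 * V_brain_total"},
    {"name": "V_LYS_total", "unit": "ul", "aggregation": "derived",
     "literature_values": [], "derivation": "0.0125 * V_ICF"},
    {"name": "V_CSF_total", "unit": "ul", "aggregation": "single",
     "literature_values": [35], "final_value": 35},
    {"name": "V_ventricles_total", "unit": "ul", "aggregation": "single",
     "literature_values": [4.8], "final_value": 4.8},
    {"name": "V_LV", "unit": "ul", "aggregation": "single",
     "literature_values": [1.0275, 0.4, 2, 0.79, 0.32, 0.46, 0.12, 0.13],
     "final_value": 4,
     "comment": "adopted as printed; mean of collected values is ~0.66 ul, flagged by validate_physiology"},
    {"name": "V_TFV", "unit": "ul", "aggregation": "single",
     "literature_values": [2.5], "final_value": 2.5},
    {"name": "V_CM", "unit": "ul", "aggregation": "single",
     "literature_values": [2.13], "final_value": 2.13,
     "comment": "rat-to-mouse scaling of CSF sub-volume ratios"},
    {"name": "V_SAS", "unit": "ul", "aggregation": "single",
     "literature_values": [16.88], "final_value": 16.88},
    {"name": "V_MV", "unit": "ul", "aggregation": "single",
     "literature_values": [5], "final_value": 5},
    {"name": "Q_CBF", "unit": "ml/min", "aggregation": "mean",
     "literature_values": [0.46134, 0.46134]},
    {"name": "Q_ECF", "unit": "ml/min", "aggregation": "mean",
     "literature_values": [0.0001248, 0.000624],
     "comment": "brain ECF bulk flow; second value based on a 0.416 g mouse brain"},
    {"name": "Q_CSF", "unit": "ml/min", "aggregation": "mean",
     "literature_values": [0.000325, 0.000361],
     "comment": "0.000361 is volume (0.040 ml) x turnover (13/day) / 1440"},
    {"name": "SA_BBB", "unit": "cm2", "aggregation": "mean",
     "literature_values": [18.78, 20.74],
     "comment": "two estimation approaches: regional SA/volume weighting, and microvessel radius x length density"},
    {"name": "SA_BCSFB", "unit": "cm2", "aggregation": "derived",
     "literature_values": [], "derivation": "0.5 * SA_BBB"},
    {"name": "SA_BCM", "unit": "cm2", "aggregation": "derived",
     "literature_values": [],
     "derivation": "monodisperse spheres from N_cells and V_ICF"},
    {"name": "SA_LYS", "unit": "cm2", "aggregation": "single",
     "literature_values": [540], "final_value": 540,
     "comment": "adopted as printed; the underlying lysosomal radius is not available"},
    {"name": "f_trans_BBB", "unit": "unitless", "aggregation": "single",
     "literature_values": [0.998], "final_value": 0.998},
    {"name": "f_trans_BCSFB", "unit": "unitless", "aggregation": "single",
     "literature_values": [0.998], "final_value": 0.998},
    {"name": "f_para_BBB", "unit": "unitless", "aggregation": "single",
     "literature_values": [0.006], "final_value": 0.006},
    {"name": "f_para_BCSFB", "unit": "unitless", "aggregation": "single",
     "literature_values": [0.05], "final_value": 0.05},
    {"name": "w_BBB", "unit": "um", "aggregation": "single",
     "literature_values": [0.7], "final_value": 0.7},
    {"name": "w_BCSFB", "unit": "um", "aggregation": "single",
     "literature_values": [1.7], "final_value": 1.7},
    {"name": "f_phospholipid", "unit": "unitless", "aggregation": "single",
     "literature_values": [0.05], "final_value": 0.05},
    {"name": "pH_plasma", "unit": "pH", "aggregation": "single",
     "literature_values": [7.4], "final_value": 7.4},
    {"name": "pH_ECF", "unit": "pH", "aggregation": "single",
     "literature_values": [7.4], "final_value": 7.4},
    {"name": "pH_ICF", "unit": "pH", "aggregation": "single",
     "literature_values": [7.2], "final_value": 7.2},
    {"name": "pH_LYS", "unit": "pH", "aggregation": "single",
     "literature_values": [4.8, 5.5, 6, 5.5, 5.6, 4.9], "final_value": 5.5,
     "comment": "adopted as printed; mean of collected values is 5.38, flagged by validate_physiology"},
    {"name": "pH_CSF", "unit": "pH", "aggregation": "single",
     "literature_values": [7.2], "final_value": 7.2},
    {"name": "N_cells", "unit": "count", "aggregation": "single",
     "literature_values": [108690000], "final_value": 108690000},
    {"name": "brain_weight", "unit": "g", "aggregation": "single",
     "literature_values": [0.416], "final_value": 0.416}
  ]
}
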