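{
  "comment": "Empirical population plasma PK parameter sets per drug (naive transcription; decimal commas normalized). Units: CL/Q2 ml/min, Vc/Vp2 ml, ka 1/min, zero_order_duration min, IIV as exponential-model variances, residual as proportional variance and additive variance (ng/ml)^2. Extravascular models with ka = 0 are treated as instantaneous absorption.",
  "models": [
    {
      "name": "cyclophosphamide",
      "dose_mg_kg": 130,
      "route": "IP",
      "fu_plasma": 0.26,
      "n_compartments": 2,
      "CL": 2.094,
      "Q2": 0.086,
      "Vc": 18.5,
      "Vp2": 1.77,
      "ka": 0,
      "zero_order_duration": 0,
      "iiv": {
        "CL": 0.012,
        "Q2": 0,
        "Vc": 0,
        "Vp2": 0,
        "ka": 0
      },
      "residual": {
        "prop": 0.058,
        "add": 0
      }
    },
    {
      "name": "quinidine",
      "dose_mg_kg": 40,
      "route": "IP",
      "fu_plasma": 0.233,
      "n_compartments": 1,
      "CL": 6.99,
      "Q2": 0,
      "Vc": 329,
      "Vp2": 0,
      "ka": 2.61,
      "zero_order_duration": 10,
      "iiv": {
        "CL": 0,
        "Q2": 0,
        "Vc": 0,
        "Vp2": 0,
        "ka": 0
      },
      "residual": {
        "prop": 0,
        "add": 2.05
      }
    },
    {
      "name": "erlotinib",
      "dose_mg_kg": 50,
      "route": "PO",
      "fu_plasma": 0.048,
      "n_compartments": 1,
      "CL": 0.412,
      "Q2": 0,
      "Vc": 51.3,
      "Vp2": 0,
      "ka": 0.012,
      "zero_order_duration": 10,
      "iiv": {
        "CL": 0,
        "Q2": 0,
        "Vc": 0,
        "Vp2": 0,
        "ka": 0.614
      },
      "residual": {
        "prop": 0.212,
        "add": 0
      }
    },
    {
      "name": "phenobarbital",
      "dose_mg_kg": 10,
      "route": "IP",
      "fu_plasma": 0.7,
      "n_compartments": 1,
      "CL": 0.02,
      "Q2": 0,
      "Vc": 147,
      "Vp2": 0,
      "ka": 0,
      "zero_order_duration": 0,
      "iiv": {
        "CL": 0,
        "Q2": 0,
        "Vc": 0,
        "Vp2": 0,
        "ka": 0
      },
      "residual": {
        "prop": 0.005,
        "add": 0
      }
    },
    {
      "name": "colchicine",
      "dose_mg_kg": 1.5,
      "route": "IV",
      "fu_plasma": 0.61,
      "n_compartments": 2,
      "CL": 0.487,
      "Q2": 2.11,
      "Vc": 11.27,
      "Vp2": 705,
      "ka": 0,
      "zero_order_duration": 0,
      "iiv": {
        "CL": 0,
        "Q2": 0,
        "Vc": 0,
        "Vp2": 0,
        "ka": 0
      },
      "residual": {
        "prop": 0.0224,
        "add": 0
      }
    },
    {
      "name": "ribociclib",
      "dose_mg_kg": 100,
      "route": "PO",
      "fu_plasma": 0.23,
      "n_compartments": 1,
      "CL": 1.32,
      "Q2": 0,
      "Vc": 0.15,
      "Vp2": 0,
      "ka": 0.046,
      "zero_order_duration": 0,
      "iiv": {
        "CL": 0.217,
        "Q2": 0,
        "Vc": 0,
        "Vp2": 0,
        "ka": 0.676
      },
      "residual": {
        "prop": 0.276,
        "add": 0
      }
    },
    {
      "name": "topotecan",
      "dose_mg_kg": 4,
      "route": "IV",
      "fu_plasma": 0.3,
      "n_compartments": 2,
      "CL": 1.41,
      "Q2": 0.486,
      "Vc": 30.1,
      "Vp2": 18.36,
      "ka": 0,
      "zero_order_duration": 0,
      "iiv": {
        "CL": 0.011,
        "Q2": 0,
        "Vc": 0,
        "Vp2": 0,
        "ka": 0
      },
      "residual": {
        "prop": 0.051,
        "add": 0
      }
    },
    {
      "name": "cefadroxil",
      "dose_mg_kg": 36,
      "route": "IV",
      "fu_plasma": 1,
      "n_compartments": 1,
      "CL": 0.97,
      "Q2": 0,
      "Vc": 8.41,
      "Vp2": 0,
      "ka": 0,
      "zero_order_duration": 0,
      "iiv": {
        "CL": 0,
        "Q2": 0,
        "Vc": 0,
        "Vp2": 0,
        "ka": 0
      },
      "residual": {
        "prop": 0,
        "add": 0
      }
    },
    {
      "name": "prexasertib",
      "dose_mg_kg": 10,
      "route": "SC",
      "fu_plasma": 0.11,
      "n_compartments": 2,
      "CL": 2.68,
      "Q2": 0.276,
      "Vc": 1451.5,
      "Vp2": 97.47,
      "ka": 0.018,
      "zero_order_duration": 0,
      "iiv": {
        "CL": 0.046,
        "Q2": 0.027,
        "Vc": 0,
        "Vp2": 0,
        "ka": 0.04
      },
      "residual": {
        "prop": 0.003,
        "add": 0
      }
    },
    {
      "name": "methotrexate",
      "dose_mg_kg": 1000,
      "route": "IV",
      "fu_plasma": 0.519,
      "n_compartments": 2,
      "CL": 0.688,
      "Q2": 0.03,
      "Vc": 99.21,
      "Vp2": 2.14,
      "ka": 0,
      "zero_order_duration": 0,
      "iiv": {
        "CL": 0.021,
        "Q2": 0,
        "Vc": 0,
        "Vp2": 0,
        "ka": 0
      },
      "residual": {
        "prop": 0.18,
        "add": 0
      }
    }
  ]
}
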