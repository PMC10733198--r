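{
  "comment": "Physicochemical and biological drug records. pKa/logP/PSA/HBA/HBD are in-silico (ALOGPS / Chemaxon style) values; fu_plasma is the plasma unbound fraction; kpuu_bbb is the unbound brain-ECF/plasma steady-state ratio with its provenance label; p_trans is a clearly-labelled placeholder passive transcellular permeability (cm/min).",
  "drugs": [
    {
      "name": "cyclophosphamide",
      "mwt": 261,
      "logp": 0.76,
      "pka_acid": [
        13.48
      ],
      "pka_base": [],
      "psa": 41.57,
      "hba": 1,
      "hbd": 1,
      "fu_plasma": 0.26,
      "kpuu_bbb": 0.339,
      "kpuu_method": "estimated",
      "p_trans": 0.004018,
      "p_trans_source": "logP placeholder estimator (synthetic; not a measured value)"
    },
    {
      "name": "quinidine",
      "mwt": 324,
      "logp": 2.82,
      "pka_acid": [
        13.89
      ],
      "pka_base": [
        9.05
      ],
      "psa": 45.59,
      "hba": 4,
      "hbd": 1,
      "fu_plasma": 0.233,
      "kpuu_bbb": 0.2185,
      "kpuu_method": "literature",
      "p_trans": 0.02679,
      "p_trans_source": "logP placeholder estimator (synthetic; not a measured value)"
    },
    {
      "name": "erlotinib",
      "mwt": 393,
      "logp": 3.13,
      "pka_acid": [
        16.14
      ],
      "pka_base": [
        4.62
      ],
      "psa": 74.73,
      "hba": 7,
      "hbd": 1,
      "fu_plasma": 0.048,
      "kpuu_bbb": 0.628,
      "kpuu_method": "estimated",
      "p_trans": 0.03565,
      "p_trans_source": "logP placeholder estimator (synthetic; not a measured value)"
    },
    {
      "name": "phenobarbital",
      "mwt": 232,
      "logp": 1.4,
      "pka_acid": [
        7.14
      ],
      "pka_base": [],
      "psa": 75.27,
      "hba": 3,
      "hbd": 2,
      "fu_plasma": 0.7,
      "kpuu_bbb": 0.0121,
      "kpuu_method": "estimated",
      "p_trans": 0.007244,
      "p_trans_source": "logP placeholder estimator (synthetic; not a measured value)"
    },
    {
      "name": "colchicine",
      "mwt": 399,
      "logp": 1.59,
      "pka_acid": [
        15.06
      ],
      "pka_base": [
        -1.26
      ],
      "psa": 83.09,
      "hba": 6,
      "hbd": 1,
      "fu_plasma": 0.61,
      "kpuu_bbb": 0.14,
      "kpuu_method": "literature",
      "p_trans": 0.00863,
      "p_trans_source": "logP placeholder estimator (synthetic; not a measured value)"
    },
    {
      "name": "ribociclib",
      "mwt": 435,
      "logp": 2.5,
      "pka_acid": [
        11.59
      ],
      "pka_base": [
        8.87
      ],
      "psa": 91.21,
      "hba": 7,
      "hbd": 2,
      "fu_plasma": 0.23,
      "kpuu_bbb": 0.0693,
      "kpuu_method": "literature",
      "p_trans": 0.01995,
      "p_trans_source": "logP placeholder estimator (synthetic; not a measured value)"
    },
    {
      "name": "topotecan",
      "mwt": 421,
      "logp": 1.84,
      "pka_acid": [
        8
      ],
      "pka_base": [
        9.75
      ],
      "psa": 103.2,
      "hba": 6,
      "hbd": 2,
      "fu_plasma": 0.3,
      "kpuu_bbb": 0.21,
      "kpuu_method": "literature",
      "p_trans": 0.01086,
      "p_trans_source": "logP placeholder estimator (synthetic; not a measured value)"
    },
    {
      "name": "cefadroxil",
      "mwt": 363,
      "logp": 0.51,
      "pka_acid": [
        3.25
      ],
      "pka_base": [
        7.22
      ],
      "psa": 132.96,
      "hba": 6,
      "hbd": 4,
      "fu_plasma": 1,
      "kpuu_bbb": 0.05,
      "kpuu_method": "estimated",
      "p_trans": 0.003192,
      "p_trans_source": "logP placeholder estimator (synthetic; not a measured value)"
    },
    {
      "name": "prexasertib",
      "mwt": 365,
      "logp": 1.77,
      "pka_acid": [
        10.02
      ],
      "pka_base": [
        9.85
      ],
      "psa": 134.76,
      "hba": 8,
      "hbd": 3,
      "fu_plasma": 0.11,
      "kpuu_bbb": 0.09,
      "kpuu_method": "literature",
      "p_trans": 0.01019,
      "p_trans_source": "logP placeholder estimator (synthetic; not a measured value)"
    },
    {
      "name": "methotrexate",
      "mwt": 454,
      "logp": -0.91,
      "pka_acid": [
        3.41
      ],
      "pka_base": [
        2.81
      ],
      "psa": 205.92,
      "hba": 12,
      "hbd": 6,
      "fu_plasma": 0.519,
      "kpuu_bbb": 0.195,
      "kpuu_method": "estimated",
      "p_trans": 0.000863,
      "p_trans_source": "logP placeholder estimator (synthetic; not a measured value)"
    }
  ]
}
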