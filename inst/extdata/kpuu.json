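{
  "comment": "Kp,uu,BBB values with provenance: literature = taken from a published study, estimated = obtained by combining a plasma PK model with a one-compartment whole-brain model.",
  "kpuu": [
    {
      "name": "cyclophosphamide",
      "kpuu_bbb": 0.339,
      "method": "estimated"
    },
    {
      "name": "quinidine",
      "kpuu_bbb": 0.2185,
      "method": "literature"
    },
    {
      "name": "erlotinib",
      "kpuu_bbb": 0.628,
      "method": "estimated"
    },
    {
      "name": "phenobarbital",
      "kpuu_bbb": 0.0121,
      "method": "estimated"
    },
    {
      "name": "colchicine",
      "kpuu_bbb": 0.14,
      "method": "literature"
    },
    {
      "name": "ribociclib",
      "kpuu_bbb": 0.0693,
      "method": "literature"
    },
    {
      "name": "topotecan",
      "kpuu_bbb": 0.21,
      "method": "literature"
    },
    {
      "name": "cefadroxil",
      "kpuu_bbb": 0.05,
      "method": "estimated"
    },
    {
      "name": "prexasertib",
      "kpuu_bbb": 0.09,
      "method": "literature"
    },
    {
      "name": "methotrexate",
      "kpuu_bbb": 0.195,
      "method": "estimated"
    }
  ]
}
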