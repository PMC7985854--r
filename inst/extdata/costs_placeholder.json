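{
  "currency": "EUR-2020",
  "synthetic": true,
  "template": false,
  "shared_divisor": 16,
  "ai_fee_per_bitewing_pair": 8,
  "fees": {
    "exam_vt": 19.15,
    "bitewing_pair": 15.62,
    "infiltration": 78.58,
    "restoration": 134.07,
    "re_restoration": 127.46,
    "repair": 55.57,
    "direct_capping": 29.73,
    "rct": 220.2,
    "crown": 315.7,
    "recrown": 320.51,
    "recement": 21.87,
    "refix": 25.79,
    "nonsurg_retreat": 390.2,
    "surg_retreat": 338.31,
    "extraction": 39.25,
    "implant_iscrown": 2440.01,
    "reimplant": 2478.23
  }
}
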