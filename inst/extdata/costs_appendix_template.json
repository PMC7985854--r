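{
  "currency": "EUR-2020",
  "synthetic": false,
  "template": true,
  "shared_divisor": 16,
  "ai_fee_per_bitewing_pair": 8,
  "fees": {
    "exam_vt": 0,
    "bitewing_pair": 0,
    "infiltration": 0,
    "restoration": 0,
    "re_restoration": 0,
    "repair": 0,
    "direct_capping": 0,
    "rct": 0,
    "crown": 0,
    "recrown": 0,
    "recement": 0,
    "refix": 0,
    "nonsurg_retreat": 0,
    "surg_retreat": 0,
    "extraction": 0,
    "implant_iscrown": 0,
    "reimplant": 0
  }
}
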