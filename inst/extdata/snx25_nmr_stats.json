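{
  "restraints": {
    "intraresidue": 716,
    "sequential": 762,
    "medium_range": 559,
    "long_range": 987,
    "total_distance": 3024,
    "phi": 110,
    "psi": 105,
    "chi": 47
  },
  "noesy": {
    "assigned": 4774,
    "total": 5199
  }
}
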