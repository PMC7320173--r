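[
  {
    "Compound": "glucose",
    "KEGG compound ID": "C00031",
    "Class": "small molecule"
  },
  {
    "Compound": "acetate",
    "KEGG compound ID": "C00033",
    "Class": "small molecule"
  },
  {
    "Compound": "cellobiose",
    "KEGG compound ID": "C00185",
    "Class": "small molecule"
  },
  {
    "Compound": "cellulose",
    "KEGG compound ID": "C00760",
    "Class": "macromolecule",
    "Degradation products": ["glucose", "cellobiose"]
  }
]
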