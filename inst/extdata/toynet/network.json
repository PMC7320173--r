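[
  {
    "id": "NJC19_00001",
    "Species": "Bacteroides fragilis",
    "Small-molecule metabolite or macromolecule": "glucose",
    "Metabolic activity": "import",
    "Ref. #": ["R1"]
  },
  {
    "id": "NJC19_00002",
    "Species": "Bacteroides fragilis",
    "Small-molecule metabolite or macromolecule": "acetate",
    "Metabolic activity": "export",
    "Ref. #": ["R1", "R2"]
  },
  {
    "id": "NJC19_00003",
    "Species": "Escherichia coli",
    "Small-molecule metabolite or macromolecule": "glucose",
    "Metabolic activity": "import",
    "Ref. #": ["R2"]
  },
  {
    "id": "NJC19_00004",
    "Species": "Escherichia coli",
    "Small-molecule metabolite or macromolecule": "acetate",
    "Metabolic activity": "export",
    "Ref. #": ["R2"]
  },
  {
    "id": "NJC19_00005",
    "Species": "Faecalibacterium prausnitzii",
    "Small-molecule metabolite or macromolecule": "cellulose",
    "Metabolic activity": "degradation",
    "Ref. #": ["R3"]
  },
  {
    "id": "NJC19_00006",
    "Species": "Faecalibacterium prausnitzii",
    "Small-molecule metabolite or macromolecule": "acetate",
    "Metabolic activity": "export",
    "Ref. #": ["R3"]
  },
  {
    "id": "NJC19_00007",
    "Species": "Escherichia coli",
    "Small-molecule metabolite or macromolecule": "cellobiose",
    "Metabolic activity": "not-import",
    "Ref. #": ["R1"]
  },
  {
    "id": "NJC19_00008",
    "Species": "intestinal absorptive cell",
    "Small-molecule metabolite or macromolecule": "glucose",
    "Metabolic activity": "import",
    "Ref. #": ["R4"]
  },
  {
    "id": "NJC19_00009",
    "Species": "Bacteroides fragilis",
    "Small-molecule metabolite or macromolecule": "cellulose",
    "Metabolic activity": "not-degradation",
    "Ref. #": ["R3"]
  },
  {
    "id": "NJC19_00010",
    "Species": "Faecalibacterium prausnitzii",
    "Small-molecule metabolite or macromolecule": "glucose",
    "Metabolic activity": "import",
    "Ref. #": ["R3", "R4"]
  }
]
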