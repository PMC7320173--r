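[
  {
    "Species": "Bacteroides fragilis",
    "NCBI taxonomy ID": 817,
    "Rank": "species",
    "Kind": "microbe",
    "Lineage": {
      "domain": "Bacteria",
      "phylum": "Bacteroidetes",
      "genus": "Bacteroides",
      "species": "Bacteroides fragilis"
    },
    "Sample sources": ["mouse cecum"]
  },
  {
    "Species": "Escherichia coli",
    "NCBI taxonomy ID": 562,
    "Rank": "species",
    "Kind": "microbe",
    "Lineage": {
      "domain": "Bacteria",
      "phylum": "Proteobacteria",
      "genus": "Escherichia",
      "species": "Escherichia coli"
    },
    "Sample sources": ["mouse feces", "human feces"]
  },
  {
    "Species": "Faecalibacterium prausnitzii",
    "NCBI taxonomy ID": 853,
    "Rank": "species",
    "Kind": "microbe",
    "Lineage": {
      "domain": "Bacteria",
      "phylum": "Firmicutes",
      "genus": "Faecalibacterium",
      "species": "Faecalibacterium prausnitzii"
    },
    "Sample sources": ["human feces"]
  },
  {
    "Species": "intestinal absorptive cell",
    "NCBI taxonomy ID": null,
    "Cell type": "intestinal absorptive cell",
    "Rank": "cell_type",
    "Kind": "host_cell",
    "Lineage": {},
    "Sample sources": []
  }
]
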