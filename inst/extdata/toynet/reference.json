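[
  {"Ref. #": "R1", "Citation": "Synthetic citation one"},
  {"Ref. #": "R2", "Citation": "Synthetic citation two"},
  {"Ref. #": "R3", "Citation": "Synthetic citation three"},
  {"Ref. #": "R4", "Citation": "Synthetic citation four"}
]
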