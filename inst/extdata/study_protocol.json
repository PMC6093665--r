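{
  "description": "Search protocol of the two-stage aetosaur analysis; used by analysis/05_replication.R.",
  "n_replicates": 100,
  "hold": 10,
  "collapse": "rule1",
  "outgroup": "Postosuchus kirkpatricki",
  "second_outgroup_display_only": "Revueltosaurus callenderi",
  "otu_merge": {
    "source": "SMNS 19003",
    "target": "Paratypothorax andressorum",
    "note": "already applied in the deposited matrix; listed for provenance"
  },
  "expected_unstable": [
    "Aetobarbakinoides brasiliensis",
    "Stenomyti huangae",
    "Polesinesuchus aurelioi"
  ],
  "a_posteriori_prune": "Coahomasuchus kahleorum",
  "ordered_characters": null,
  "ordered_characters_note": "Seven characters are additive; their identity comes from the source matrix publication and must be present as a ccode/TYPESET declaration in the matrix file. Replication mode refuses to run without one."
}
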