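{
  "name": "ALT",
  "sink": "telomere_elongation_alt",
  "nodes": [
    {"id": "ddr_sensors", "label": "DNA damage checkpoint kinases", "kind": "input",
     "genes": ["ATM", "ATR", "CHEK1", "CHEK2"]},
    {"id": "mrn_complex", "label": "MRN complex", "kind": "input",
     "genes": ["MRE11", "RAD50", "NBN"]},
    {"id": "dna_damage_response", "label": "DNA damage response at telomeres", "kind": "intermediate",
     "genes": ["H2AX"], "branch": "DNA damage response"},
    {"id": "pml_body_factors", "label": "PML nuclear body scaffold", "kind": "input",
     "genes": ["PML", "SP100", "MDC1"]},
    {"id": "sumoylation", "label": "SUMO conjugation machinery", "kind": "input",
     "genes": ["SUMO1", "SUMO2", "UBE2I"]},
    {"id": "apb_formation", "label": "APB formation", "kind": "complex",
     "genes": [], "branch": "APB formation"},
    {"id": "smc5_6_complex", "label": "SMC5/6 sumoylation complex", "kind": "input",
     "genes": ["SMC5", "SMC6", "NSMCE2"]},
    {"id": "telomere_recruitment_apb", "label": "telomere recruitment to APB", "kind": "complex",
     "genes": [], "branch": "telomere recruitment to APB"},
    {"id": "recombinases", "label": "homologous recombination effectors", "kind": "input",
     "genes": ["RAD51", "RAD52", "RAD51AP1", "BRCA2"]},
    {"id": "rpa_complex", "label": "RPA single-strand binding complex", "kind": "input",
     "genes": ["RPA1", "RPA2", "RPA3"]},
    {"id": "strand_invasion", "label": "strand invasion", "kind": "linker",
     "genes": [], "branch": "strand invasion"},
    {"id": "pol_delta", "label": "DNA polymerase delta holoenzyme", "kind": "input",
     "genes": ["POLD1", "POLD2", "POLD3", "POLD4", "PCNA", "RFC1"]},
    {"id": "templated_synthesis", "label": "templated telomere synthesis", "kind": "linker",
     "genes": [], "branch": "templated synthesis"},
    {"id": "holliday_junction_processing", "label": "Holliday junction dissolution/resolution", "kind": "intermediate",
     "genes": ["BLM", "TOP3A", "RMI1", "RMI2", "GEN1", "SLX4", "MUS81"],
     "branch": "Holliday junction processing"},
    {"id": "telomere_elongation_alt", "label": "telomere elongation (ALT output)", "kind": "sink",
     "genes": []}
  ],
  "edges": [
    {"source": "ddr_sensors", "target": "dna_damage_response", "sign": "activation", "weight": 1},
    {"source": "mrn_complex", "target": "dna_damage_response", "sign": "activation", "weight": 1},
    {"source": "pml_body_factors", "target": "apb_formation", "sign": "activation", "weight": 1},
    {"source": "sumoylation", "target": "apb_formation", "sign": "activation", "weight": 1},
    {"source": "dna_damage_response", "target": "apb_formation", "sign": "activation", "weight": 1},
    {"source": "apb_formation", "target": "telomere_recruitment_apb", "sign": "activation", "weight": 1},
    {"source": "smc5_6_complex", "target": "telomere_recruitment_apb", "sign": "activation", "weight": 1},
    {"source": "telomere_recruitment_apb", "target": "strand_invasion", "sign": "activation", "weight": 1},
    {"source": "recombinases", "target": "strand_invasion", "sign": "activation", "weight": 1},
    {"source": "rpa_complex", "target": "strand_invasion", "sign": "activation", "weight": 1},
    {"source": "strand_invasion", "target": "templated_synthesis", "sign": "activation", "weight": 1},
    {"source": "pol_delta", "target": "templated_synthesis", "sign": "activation", "weight": 1},
    {"source": "templated_synthesis", "target": "holliday_junction_processing", "sign": "activation", "weight": 1},
    {"source": "holliday_junction_processing", "target": "telomere_elongation_alt", "sign": "activation", "weight": 1}
  ]
}
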