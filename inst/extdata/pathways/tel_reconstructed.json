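{
  "name": "TEL",
  "sink": "telomere_synthesis",
  "nodes": [
    {"id": "tert_activators", "label": "TERT transcriptional activators", "kind": "input",
     "genes": ["MYC", "MAX", "SP1", "HIF1A", "ESR1"]},
    {"id": "tert", "label": "TERT expression", "kind": "intermediate",
     "genes": ["TERT"], "branch": "TERT"},
    {"id": "terc", "label": "TERC expression", "kind": "input",
     "genes": ["TERC"], "branch": "TERC"},
    {"id": "dyskerin", "label": "dyskerin complex", "kind": "input",
     "genes": ["DKC1", "NOP10", "NHP2", "GAR1"], "branch": "dyskerin"},
    {"id": "assembly_factors", "label": "telomerase assembly and trafficking factors", "kind": "input",
     "genes": ["RUVBL1", "RUVBL2", "WRAP53"]},
    {"id": "telomerase_complex", "label": "catalytically active telomerase complex", "kind": "complex",
     "genes": [], "branch": "telomerase assembly"},
    {"id": "shelterin", "label": "shelterin complex", "kind": "input",
     "genes": ["TINF2", "ACD", "POT1", "TERF1", "TERF2", "TERF2IP"]},
    {"id": "telomere_recruitment", "label": "telomerase recruitment to telomeres", "kind": "complex",
     "genes": [], "branch": "telomere recruitment"},
    {"id": "pol_alpha_primase", "label": "DNA polymerase alpha-primase", "kind": "input",
     "genes": ["POLA1", "POLA2", "PRIM1", "PRIM2"]},
    {"id": "cst_complex", "label": "CST fill-in complex", "kind": "input",
     "genes": ["CTC1", "STN1"]},
    {"id": "telomere_synthesis", "label": "telomere synthesis (TEL output)", "kind": "sink",
     "genes": []}
  ],
  "edges": [
    {"source": "tert_activators", "target": "tert", "sign": "activation", "weight": 1},
    {"source": "tert", "target": "telomerase_complex", "sign": "activation", "weight": 1},
    {"source": "terc", "target": "telomerase_complex", "sign": "activation", "weight": 1},
    {"source": "dyskerin", "target": "telomerase_complex", "sign": "activation", "weight": 1},
    {"source": "assembly_factors", "target": "telomerase_complex", "sign": "activation", "weight": 1},
    {"source": "telomerase_complex", "target": "telomere_recruitment", "sign": "activation", "weight": 1},
    {"source": "shelterin", "target": "telomere_recruitment", "sign": "activation", "weight": 1},
    {"source": "telomere_recruitment", "target": "telomere_synthesis", "sign": "activation", "weight": 1},
    {"source": "pol_alpha_primase", "target": "telomere_synthesis", "sign": "activation", "weight": 1},
    {"source": "cst_complex", "target": "telomere_synthesis", "sign": "activation", "weight": 1}
  ]
}
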