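{
  "modality": "anterior",
  "nodes": [
    {"id": "demo_root", "name": "Demo modality (root)", "level": 0, "parent": null},
    {"id": "group_a", "name": "Disease group A", "level": 1, "parent": "demo_root"},
    {"id": "group_b", "name": "Disease group B", "level": 1, "parent": "demo_root"},
    {"id": "a1", "name": "Subtype A1", "level": 2, "parent": "group_a"},
    {"id": "a2", "name": "Subtype A2", "level": 2, "parent": "group_a"},
    {"id": "b1", "name": "Subtype B1", "level": 2, "parent": "group_b"},
    {"id": "b2", "name": "Subtype B2", "level": 2, "parent": "group_b"}
  ],
  "class_order": {
    "1": ["group_a", "group_b"],
    "2": ["a1", "a2", "b1", "b2"]
  }
}
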