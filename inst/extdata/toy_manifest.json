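{
  "run_id": "toy_run",
  "sites": [
    {"site_id": "RiverA", "water_body_type": "river"},
    {"site_id": "RiverB", "water_body_type": "river"},
    {"site_id": "RiverC", "water_body_type": "river"},
    {"site_id": "LakeA", "water_body_type": "lake"},
    {"site_id": "LakeB", "water_body_type": "lake"},
    {"site_id": "ReservoirA", "water_body_type": "reservoir"}
  ],
  "events": [
    {"event_index": 1, "label": "2018-06-04"},
    {"event_index": 2, "label": "2018-06-18"},
    {"event_index": 3, "label": "2018-07-02"},
    {"event_index": 4, "label": "2018-07-16"},
    {"event_index": 5, "label": "2018-07-30"},
    {"event_index": 6, "label": "2018-08-13"},
    {"event_index": 7, "label": "2018-08-27"},
    {"event_index": 8, "label": "2018-09-10"},
    {"event_index": 9, "label": "2018-09-24"},
    {"event_index": 10, "label": "2018-10-08"}
  ],
  "replicates_per_event": 6,
  "controls": [
    {"sample_id": "Plate1_POS", "kind": "positive",
     "expected_taxa": ["Dreissena rostriformis", "Dreissena polymorpha"]},
    {"sample_id": "Plate1_NEG", "kind": "negative", "expected_taxa": []}
  ]
}
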