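{
  "passage_id": "toy-tavern",
  "roots": ["P1", "P2"],
  "synonyms": {
    "storm": ["tempest", "gale"],
    "captain": ["skipper"]
  },
  "propositions": [
    {"id": "P1", "predicate": "sail", "args": ["captain"]},
    {"id": "P2", "predicate": "storm", "args": ["sea"]},
    {"id": "P3", "predicate": "brave", "args": ["P1", "captain"]},
    {"id": "P4", "predicate": "old", "args": ["P2"]},
    {"id": "P5", "predicate": "grey", "args": ["P3", "beard"]},
    {"id": "P6", "predicate": "howl", "args": ["wind"]}
  ]
}
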