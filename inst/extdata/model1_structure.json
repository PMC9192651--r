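{
  "schema": "suidbn-structure",
  "version": 1,
  "model_id": 1,
  "direction": "causal",
  "outcome": "cause_of_death",
  "comment": "Causal orientation: risk factors upstream, outcome downstream. Age band, death during sleep and co-sleeping are the proximal parents of the outcome; distal factors (breastfeeding, maternal age, gestational age, passive smoking) act through intermediates. Editable transcription: the pipeline is structure-agnostic.",
  "nodes": {
    "age_band": ["0-2", "3-6", "7-11"],
    "sex": ["male", "female"],
    "gestational_age": ["<37", ">=37"],
    "birth_weight": ["<2500", ">=2500"],
    "death_during_sleep": ["yes", "no"],
    "co_sleeping": ["yes", "no", "na"],
    "sleep_position": ["supine", "prone", "other", "unknown", "na"],
    "maternal_age": ["<19", "20-34", ">=35"],
    "siblings": ["0", "1", ">=2"],
    "suid_history": ["yes", "no"],
    "breastfeeding": ["yes", "no", "unknown"],
    "passive_smoking": ["yes", "no", "unknown"],
    "alcohol": ["yes", "no"],
    "vaccination": ["yes", "no", "unknown"],
    "maltreatment": ["yes", "no"],
    "infection_symptoms": ["yes", "no"],
    "cause_of_death": ["SIDS", "non_SIDS"]
  },
  "edges": [
    {"from": "age_band", "to": "cause_of_death"},
    {"from": "death_during_sleep", "to": "cause_of_death"},
    {"from": "co_sleeping", "to": "cause_of_death"},
    {"from": "death_during_sleep", "to": "co_sleeping"},
    {"from": "breastfeeding", "to": "co_sleeping"},
    {"from": "death_during_sleep", "to": "sleep_position"},
    {"from": "gestational_age", "to": "birth_weight"},
    {"from": "maternal_age", "to": "breastfeeding"},
    {"from": "passive_smoking", "to": "infection_symptoms"}
  ]
}
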