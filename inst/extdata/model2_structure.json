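{
  "schema": "suidbn-structure",
  "version": 1,
  "model_id": 2,
  "direction": "retrospective",
  "outcome": "cause_of_death",
  "comment": "Retrospective orientation: the cause of death is estimated from factors observed after the fact, so edges run outcome -> factor; the structural nesting of co-sleeping and sleeping position under death-during-sleep is kept. Editable transcription: the pipeline is structure-agnostic.",
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
    {"from": "cause_of_death", "to": "age_band"},
    {"from": "cause_of_death", "to": "sex"},
    {"from": "cause_of_death", "to": "gestational_age"},
    {"from": "cause_of_death", "to": "birth_weight"},
    {"from": "cause_of_death", "to": "death_during_sleep"},
    {"from": "cause_of_death", "to": "co_sleeping"},
    {"from": "cause_of_death", "to": "sleep_position"},
    {"from": "cause_of_death", "to": "maternal_age"},
    {"from": "cause_of_death", "to": "siblings"},
    {"from": "cause_of_death", "to": "suid_history"},
    {"from": "cause_of_death", "to": "breastfeeding"},
    {"from": "cause_of_death", "to": "passive_smoking"},
    {"from": "cause_of_death", "to": "alcohol"},
    {"from": "cause_of_death", "to": "vaccination"},
    {"from": "cause_of_death", "to": "maltreatment"},
    {"from": "cause_of_death", "to": "infection_symptoms"},
    {"from": "death_during_sleep", "to": "co_sleeping"},
    {"from": "death_during_sleep", "to": "sleep_position"}
  ]
}
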