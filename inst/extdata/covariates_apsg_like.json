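[
  {
    "name": "age",
    "kind": "continuous",
    "unit": "years",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "female",
    "kind": "binary",
    "unit": "",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "outpatient",
    "kind": "binary",
    "unit": "",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "prior_hospitalization",
    "kind": "binary",
    "unit": "",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "nursing_home",
    "kind": "binary",
    "unit": "",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "dialysis",
    "kind": "binary",
    "unit": "",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "diabetes",
    "kind": "binary",
    "unit": "",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "heart_failure",
    "kind": "binary",
    "unit": "",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "liver_disease",
    "kind": "binary",
    "unit": "",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "renal_disease",
    "kind": "binary",
    "unit": "",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "dementia",
    "kind": "binary",
    "unit": "",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "malignancy",
    "kind": "binary",
    "unit": "",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "asthma",
    "kind": "binary",
    "unit": "",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "copd_bronchiectasis",
    "kind": "binary",
    "unit": "",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "oral_steroids",
    "kind": "binary",
    "unit": "",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "antacids",
    "kind": "binary",
    "unit": "",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "sleep_drugs",
    "kind": "binary",
    "unit": "",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "aspiration_episodes",
    "kind": "binary",
    "unit": "",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "preexisting_impaired_consciousness",
    "kind": "binary",
    "unit": "",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "neuromuscular_disease",
    "kind": "binary",
    "unit": "",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "device_insertion",
    "kind": "binary",
    "unit": "",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "cerebrovascular_disease",
    "kind": "binary",
    "unit": "",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "bedridden",
    "kind": "binary",
    "unit": "",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "impaired_consciousness",
    "kind": "binary",
    "unit": "",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "heart_rate",
    "kind": "continuous",
    "unit": "beats/min",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "respiratory_rate",
    "kind": "continuous",
    "unit": "breaths/min",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "systolic_bp",
    "kind": "continuous",
    "unit": "mmHg",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "body_temperature",
    "kind": "continuous",
    "unit": "degC",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "hematocrit",
    "kind": "continuous",
    "unit": "%",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "bun",
    "kind": "continuous",
    "unit": "mg/dL",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "sodium",
    "kind": "continuous",
    "unit": "mEq/L",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "glucose",
    "kind": "continuous",
    "unit": "mg/dL",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "albumin",
    "kind": "continuous",
    "unit": "g/dL",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "pleural_effusion",
    "kind": "binary",
    "unit": "",
    "levels": null,
    "in_propensity_model": true
  },
  {
    "name": "hospital",
    "kind": "categorical",
    "unit": "",
    "levels": ["site_A", "site_B", "site_C", "site_D"],
    "in_propensity_model": false
  },
  {
    "name": "micro_blood",
    "kind": "binary",
    "unit": "",
    "levels": null,
    "in_propensity_model": false
  },
  {
    "name": "micro_pleural",
    "kind": "binary",
    "unit": "",
    "levels": null,
    "in_propensity_model": false
  },
  {
    "name": "sputum_quality",
    "kind": "binary",
    "unit": "",
    "levels": null,
    "in_propensity_model": false
  },
  {
    "name": "sputum_cfu",
    "kind": "continuous",
    "unit": "CFU/mL",
    "levels": null,
    "in_propensity_model": false
  },
  {
    "name": "sputum_semiquant",
    "kind": "continuous",
    "unit": "score 0-3",
    "levels": null,
    "in_propensity_model": false
  },
  {
    "name": "micro_urinary",
    "kind": "binary",
    "unit": "",
    "levels": null,
    "in_propensity_model": false
  }
]
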