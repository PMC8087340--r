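{
  "name": "default_v1",
  "met_vigorous": 8.0,
  "met_moderate": 4.0,
  "met_walk": 3.3,
  "daily_cap_minutes": 180,
  "activity_ref_met": 3000,
  "social_degree_weight": 0.5,
  "social_degree_ref": 10,
  "wakastatus_weights": {
    "diet": 0.25,
    "activity": 0.25,
    "bmi": 0.25,
    "social": 0.25
  },
  "fixedpoint_tol": 1e-9,
  "fixedpoint_max_iter": 1000
}
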