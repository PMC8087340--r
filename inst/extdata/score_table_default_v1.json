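{
  "name": "default_v1",
  "comment": "Per-item penalty points (1 = healthiest, 10 = least healthy) by item class and weekly frequency level L0..L5. Daily-recommended foods are penalised when absent, weekly-recommended foods when absent or excessive, occasional foods when frequent. Provisional defaults: the deployed instrument's per-item tables are not public.",
  "penalties": {
    "daily":      [10, 8, 6, 4, 2, 1],
    "weekly":     [8, 5, 2, 1, 4, 7],
    "occasional": [1, 2, 4, 6, 8, 10]
  },
  "level_upper_bounds": [0, 1, 3, 7, 14, null],
  "level_representative_units": [0, 0.5, 2, 4.5, 9, 16]
}
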