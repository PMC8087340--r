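{
  "name": "pilot2019",
  "n": 74,
  "female_fraction": 0.7297297297297297,
  "age": { "mean": 20.7, "sd": 2.5 },
  "bmi": { "mean": 21.4, "sd": 2.41, "lower": 14, "upper": 45 },
  "height": {
    "female": { "mean": 1.64, "sd": 0.06 },
    "male":   { "mean": 1.77, "sd": 0.07 },
    "other":  { "mean": 1.70, "sd": 0.08 }
  },
  "sleep": { "mean": 7.02, "sd": 0.8 },
  "cigarettes_mean": 0.6,
  "disease_prevalence": 0,
  "n_zip_areas": 55,
  "food_weekly_means": {
    "seafood": 0.54,
    "soft_drinks": 0.62,
    "butter": 0.67,
    "alcohol": 0.78,
    "french_fries": 1.18,
    "sweetmeats": 1.22,
    "blue_fish": 1.64,
    "rice": 2.04,
    "legumes": 2.04,
    "white_fish": 2.07,
    "sausage": 2.13,
    "meats": 2.27,
    "other_oils": 2.36,
    "cheeses": 2.43,
    "nuts": 2.65,
    "fruits": 2.83,
    "vegetables": 3.17,
    "cereals": 3.17,
    "milk": 4.43,
    "olive_oil": 12.72
  },
  "activity": {
    "vigorous_days": 2.34,
    "vigorous_minutes": 33.97,
    "moderate_days": 5.11,
    "moderate_minutes": 35.76,
    "walk_days": 5.80,
    "walk_minutes": 34.26,
    "sitting_hours": 30.57
  },
  "network": {
    "mean_degree": 4.810810810810811,
    "n_blocks": 12,
    "within_prob": 0.9,
    "between_prob": null,
    "isolated_fraction": 0.06756756756756757,
    "type_probs": { "friend": 0.4, "family": 0.3, "work": 0.2, "home": 0.1 }
  },
  "seed": 0
}
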