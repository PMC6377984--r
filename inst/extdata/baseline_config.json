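{
  "description": "Baseline parameter set: bariatric surgery vs conventional medical management in morbidly obese type-2 diabetes, Thai healthcare payer perspective, costs in 2017 THB. Year-1 outcome probabilities per arm; years-2+ dynamics are a parametric assumption (alive states persist except an annual remission->improved relapse of 0.05 and a flat 0.0001 annual death probability) because no published annual transition matrix exists for this population. The persistent-state drug bundle (metformin + sulfonylurea) and the uncontrolled bundle (metformin + sulfonylurea + insulin + complication management) are likewise documented assumptions.",
  "arms": {
    "surgery": {
      "year1_probabilities": {
        "remission": 0.8356,
        "improved": 0.0411,
        "persistent": 0.0099,
        "uncontrolled": 0.1233,
        "dead": 0.0001
      },
      "one_time_cost_items": ["surgery"],
      "transition": {
        "relapse_probability": 0.05,
        "death_probability": 0.0001
      }
    },
    "no_surgery": {
      "year1_probabilities": {
        "remission": 0.0001,
        "improved": 0.23,
        "persistent": 0.17,
        "uncontrolled": 0.5998,
        "dead": 0.0001
      },
      "one_time_cost_items": [],
      "transition": {
        "relapse_probability": 0.05,
        "death_probability": 0.0001
      }
    }
  },
  "unit_costs": {
    "surgery": 150000,
    "metformin": 538.6,
    "sulfonylurea": 162,
    "thiazolidinedione": 12840,
    "alpha_glucosidase_inhibitor": 1155.6,
    "insulin": 3480,
    "supplementation": 396,
    "complication_management": 15326.4
  },
  "state_cost_composition": {
    "remission": ["supplementation"],
    "improved": ["metformin"],
    "persistent": ["metformin", "sulfonylurea"],
    "uncontrolled": ["metformin", "sulfonylurea", "insulin", "complication_management"],
    "dead": []
  },
  "utilities": {
    "remission": 0.83,
    "improved": 0.80,
    "persistent": 0.78,
    "uncontrolled": 0.75,
    "dead": 0
  },
  "discount_rate": 0.03,
  "effect_discount_rate": 0.03,
  "horizon_years": 50,
  "wtp_band": [150000, 200000],
  "cpi_base_year": 2017,
  "parameter_ranges": {
    "cost.surgery": [126200, 157500],
    "cost.metformin": [269, 3331],
    "cost.sulfonylurea": [154, 168],
    "cost.thiazolidinedione": [6420, 25680],
    "cost.alpha_glucosidase_inhibitor": [577.8, 1964.4],
    "cost.insulin": [2040, 7680],
    "cost.supplementation": [367.2, 568.8],
    "cost.complication_management": [3672, 25895],
    "prob.surgery.remission": [0.7446, 0.9101],
    "prob.no_surgery.uncontrolled": [0.53982, 0.65978],
    "utility.remission": [0.747, 0.913],
    "utility.improved": [0.72, 0.88],
    "utility.persistent": [0.702, 0.858],
    "utility.uncontrolled": [0.675, 0.825],
    "discount_rate": [0.027, 0.033],
    "transition.surgery.relapse_probability": [0.045, 0.055]
  }
}
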