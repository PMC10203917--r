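{
  "kcal_per_tsp_sugar": 16,
  "kcal_per_g_fat": 9,
  "components": [
    {
      "component": "total_fruits",
      "direction": "adequacy",
      "max_points": 5,
      "min_std": 0,
      "max_std": 0.8,
      "density": "per1000"
    },
    {
      "component": "whole_fruits",
      "direction": "adequacy",
      "max_points": 5,
      "min_std": 0,
      "max_std": 0.4,
      "density": "per1000"
    },
    {
      "component": "total_veg",
      "direction": "adequacy",
      "max_points": 5,
      "min_std": 0,
      "max_std": 1.1,
      "density": "per1000"
    },
    {
      "component": "greens_beans",
      "direction": "adequacy",
      "max_points": 5,
      "min_std": 0,
      "max_std": 0.2,
      "density": "per1000"
    },
    {
      "component": "whole_grains",
      "direction": "adequacy",
      "max_points": 10,
      "min_std": 0,
      "max_std": 1.5,
      "density": "per1000"
    },
    {
      "component": "dairy",
      "direction": "adequacy",
      "max_points": 10,
      "min_std": 0,
      "max_std": 1.3,
      "density": "per1000"
    },
    {
      "component": "total_protein",
      "direction": "adequacy",
      "max_points": 5,
      "min_std": 0,
      "max_std": 2.5,
      "density": "per1000"
    },
    {
      "component": "seafood_plant_protein",
      "direction": "adequacy",
      "max_points": 5,
      "min_std": 0,
      "max_std": 0.8,
      "density": "per1000"
    },
    {
      "component": "fatty_acids",
      "direction": "adequacy",
      "max_points": 10,
      "min_std": 1.2,
      "max_std": 2.5,
      "density": "fa_ratio"
    },
    {
      "component": "refined_grains",
      "direction": "moderation",
      "max_points": 10,
      "min_std": 1.8,
      "max_std": 4.3,
      "density": "per1000"
    },
    {
      "component": "sodium",
      "direction": "moderation",
      "max_points": 10,
      "min_std": 1.1,
      "max_std": 2,
      "density": "per1000"
    },
    {
      "component": "added_sugars",
      "direction": "moderation",
      "max_points": 10,
      "min_std": 6.5,
      "max_std": 26,
      "density": "pct_energy"
    },
    {
      "component": "sat_fat",
      "direction": "moderation",
      "max_points": 10,
      "min_std": 8,
      "max_std": 16,
      "density": "pct_energy"
    }
  ]
}
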