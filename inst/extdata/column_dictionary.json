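{
  "subjects.csv": {
    "subject_id": "unique subject identifier",
    "age_band": "randomization stratum: under13 or at_least_13 years",
    "hba1c_band": "randomization stratum: under8.5 or at_least_8.5 percent",
    "regimen": "randomization stratum: injection or pump",
    "arm": "treatment or control",
    "withdrawal_month": "month of last attended visit for withdrawn subjects; empty if retained"
  },
  "diet_days.csv": {
    "subject_id": "unique subject identifier",
    "visit_month": "months since baseline of the diet-assessment visit",
    "day_index": "record day within the visit, 1-3",
    "energy_kcal": "total energy, kcal/day",
    "total_fruit": "cup equivalents/day",
    "whole_fruit": "cup equivalents/day",
    "total_vegetables": "cup equivalents/day",
    "dark_green_orange_veg": "cup equivalents/day",
    "legumes": "cup equivalents/day",
    "total_grains": "ounce equivalents/day",
    "whole_grains": "ounce equivalents/day",
    "milk": "cup equivalents/day",
    "meat_beans": "ounce equivalents/day",
    "oils": "grams/day",
    "saturated_fat": "grams/day",
    "sodium": "milligrams/day",
    "sofaas_energy": "energy from solid fats, alcohol and added sugars, kcal/day",
    "nuts_seeds": "cup equivalents/day",
    "carbohydrate": "grams/day",
    "protein": "grams/day",
    "fat": "grams/day"
  },
  "hba1c.csv": {
    "subject_id": "unique subject identifier",
    "visit_month": "months since baseline of the HbA1c measurement",
    "hba1c_pct": "glycated hemoglobin, percent"
  }
}
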