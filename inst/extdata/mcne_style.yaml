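# Illustrative committee-style front-of-package criteria set.
# Structure: 19 food categories; cut-offs on energy, saturated fat, trans
# fat, ADDED sugar, sodium and fiber, per 100 g/100 mL or as % of energy /
# % of total fat. The numeric limits below are plausible demonstration
# values chosen by the package authors, not any authority's published
# cut-offs.
name: mcne_style
categories:
  - category: dairy_products
    eligible: true
    thresholds:
      - {nutrient: saturated_fat, cmp: "<=", limit: 15, per: pct_of_energy}
      - {nutrient: trans_fat, cmp: "<=", limit: 1, per: pct_of_total_fat}
      - {nutrient: added_sugar, cmp: "<=", limit: 5, per: per_100_basis}
      - {nutrient: sodium, cmp: "<=", limit: 300, per: per_100_basis}
  - category: dairy_drinks
    eligible: true
    thresholds:
      - {nutrient: energy, cmp: "<=", limit: 75, per: per_100_basis}
      - {nutrient: saturated_fat, cmp: "<=", limit: 1.5, per: per_100_basis}
      - {nutrient: added_sugar, cmp: "<=", limit: 5, per: per_100_basis}
  - category: fats_oils
    eligible: true
    thresholds:
      - {nutrient: saturated_fat, cmp: "<=", limit: 30, per: pct_of_total_fat}
      - {nutrient: trans_fat, cmp: "<=", limit: 1, per: pct_of_total_fat}
      - {nutrient: sodium, cmp: "<=", limit: 400, per: per_100_basis}
  - category: bread_tortillas
    eligible: true
    thresholds:
      - {nutrient: added_sugar, cmp: "<=", limit: 10, per: pct_of_energy}
      - {nutrient: sodium, cmp: "<=", limit: 400, per: per_100_basis}
      - {nutrient: fiber, cmp: ">=", limit: 3, per: per_100_basis}
  - category: breakfast_cereals
    eligible: true
    thresholds:
      - {nutrient: added_sugar, cmp: "<=", limit: 20, per: pct_of_energy}
      - {nutrient: sodium, cmp: "<=", limit: 400, per: per_100_basis}
      - {nutrient: fiber, cmp: ">=", limit: 4, per: per_100_basis}
  - category: cookies_pastries
    eligible: true
    thresholds:
      - {nutrient: energy, cmp: "<=", limit: 400, per: per_100_basis}
      - {nutrient: saturated_fat, cmp: "<=", limit: 10, per: pct_of_energy}
      - {nutrient: trans_fat, cmp: "<=", limit: 1, per: pct_of_total_fat}
      - {nutrient: added_sugar, cmp: "<=", limit: 15, per: per_100_basis}
      - {nutrient: sodium, cmp: "<=", limit: 350, per: per_100_basis}
  - category: cereal_bars
    eligible: true
    thresholds:
      - {nutrient: energy, cmp: "<=", limit: 380, per: per_100_basis}
      - {nutrient: added_sugar, cmp: "<=", limit: 18, per: per_100_basis}
      - {nutrient: fiber, cmp: ">=", limit: 3, per: per_100_basis}
  - category: salty_snacks
    eligible: true
    thresholds:
      - {nutrient: saturated_fat, cmp: "<=", limit: 10, per: pct_of_energy}
      - {nutrient: trans_fat, cmp: "<=", limit: 1, per: pct_of_total_fat}
      - {nutrient: sodium, cmp: "<=", limit: 500, per: per_100_basis}
  - category: soups_broths
    eligible: true
    thresholds:
      - {nutrient: energy, cmp: "<=", limit: 100, per: per_100_basis}
      - {nutrient: sodium, cmp: "<=", limit: 350, per: per_100_basis}
  - category: processed_meats
    eligible: true
    thresholds:
      - {nutrient: saturated_fat, cmp: "<=", limit: 5, per: per_100_basis}
      - {nutrient: sodium, cmp: "<=", limit: 700, per: per_100_basis}
  - category: cheeses
    eligible: true
    thresholds:
      - {nutrient: saturated_fat, cmp: "<=", limit: 12, per: per_100_basis}
      - {nutrient: sodium, cmp: "<=", limit: 600, per: per_100_basis}
  - category: non_caloric_beverages
    eligible: true
    thresholds:
      - {nutrient: energy, cmp: "<=", limit: 20, per: per_100_basis}
      - {nutrient: added_sugar, cmp: "<=", limit: 0.5, per: per_100_basis}
  - category: fruit_vegetable_juices
    eligible: true
    thresholds:
      - {nutrient: energy, cmp: "<=", limit: 50, per: per_100_basis}
      - {nutrient: added_sugar, cmp: "<=", limit: 0.5, per: per_100_basis}
  - category: sugar_sweetened_beverages
    eligible: true
    thresholds:
      - {nutrient: energy, cmp: "<=", limit: 20, per: per_100_basis}
      - {nutrient: added_sugar, cmp: "<=", limit: 2.5, per: per_100_basis}
  - category: sauces_dressings
    eligible: true
    thresholds:
      - {nutrient: added_sugar, cmp: "<=", limit: 8, per: per_100_basis}
      - {nutrient: sodium, cmp: "<=", limit: 750, per: per_100_basis}
  - category: ready_meals
    eligible: true
    thresholds:
      - {nutrient: energy, cmp: "<=", limit: 225, per: per_100_basis}
      - {nutrient: saturated_fat, cmp: "<=", limit: 10, per: pct_of_energy}
      - {nutrient: sodium, cmp: "<=", limit: 450, per: per_100_basis}
  - category: desserts
    eligible: true
    thresholds:
      - {nutrient: energy, cmp: "<=", limit: 250, per: per_100_basis}
      - {nutrient: saturated_fat, cmp: "<=", limit: 10, per: pct_of_energy}
      - {nutrient: added_sugar, cmp: "<=", limit: 15, per: per_100_basis}
  - category: confectionery
    eligible: true
    thresholds:
      - {nutrient: energy, cmp: "<=", limit: 350, per: per_100_basis}
      - {nutrient: added_sugar, cmp: "<=", limit: 20, per: per_100_basis}
      - {nutrient: saturated_fat, cmp: "<=", limit: 10, per: pct_of_energy}
  - category: composite_dishes
    eligible: true
    thresholds:
      - {nutrient: saturated_fat, cmp: "<=", limit: 10, per: pct_of_energy}
      - {nutrient: added_sugar, cmp: "<=", limit: 10, per: pct_of_energy}
      - {nutrient: sodium, cmp: "<=", limit: 400, per: per_100_basis}
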