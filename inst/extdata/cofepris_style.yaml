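# Illustrative regulatory-style front-of-package criteria set.
# Structure: 26 food categories; limits on energy, saturated fat, TOTAL
# sugar and sodium per 100 g/100 mL, per serving, or as % of total fat or
# energy; sugar-based categories (soft drinks, jam, jelly, syrup, honey,
# chocolate products) are ineligible to carry the logo at all. The numeric
# limits are plausible demonstration values chosen by the package authors,
# not any authority's published cut-offs.
name: cofepris_style
categories:
  - category: soft_drinks
    eligible: false
  - category: jam
    eligible: false
  - category: jelly
    eligible: false
  - category: syrup
    eligible: false
  - category: honey
    eligible: false
  - category: chocolate_products
    eligible: false
  - category: dairy_products
    eligible: true
    thresholds:
      - {nutrient: saturated_fat, cmp: "<=", limit: 18, per: pct_of_energy}
      - {nutrient: total_sugar, cmp: "<=", limit: 14, per: per_100_basis}
      - {nutrient: sodium, cmp: "<=", limit: 400, per: per_100_basis}
  - category: dairy_drinks
    eligible: true
    thresholds:
      - {nutrient: energy, cmp: "<=", limit: 90, per: per_100_basis}
      - {nutrient: total_sugar, cmp: "<=", limit: 13, per: per_100_basis}
  - category: fats_oils
    eligible: true
    thresholds:
      - {nutrient: saturated_fat, cmp: "<=", limit: 33, per: pct_of_total_fat}
      - {nutrient: sodium, cmp: "<=", limit: 500, per: per_100_basis}
  - category: bread_tortillas
    eligible: true
    thresholds:
      - {nutrient: total_sugar, cmp: "<=", limit: 15, per: per_100_basis}
      - {nutrient: sodium, cmp: "<=", limit: 500, per: per_100_basis}
  - category: breakfast_cereals
    eligible: true
    thresholds:
      - {nutrient: total_sugar, cmp: "<=", limit: 9, per: per_serving}
      - {nutrient: sodium, cmp: "<=", limit: 500, per: per_100_basis}
  - category: cookies_pastries
    eligible: true
    thresholds:
      - {nutrient: energy, cmp: "<=", limit: 200, per: per_serving}
      - {nutrient: saturated_fat, cmp: "<=", limit: 13, per: pct_of_energy}
      - {nutrient: total_sugar, cmp: "<=", limit: 25, per: per_100_basis}
  - category: cereal_bars
    eligible: true
    thresholds:
      - {nutrient: energy, cmp: "<=", limit: 130, per: per_serving}
      - {nutrient: total_sugar, cmp: "<=", limit: 30, per: per_100_basis}
  - category: salty_snacks
    eligible: true
    thresholds:
      - {nutrient: saturated_fat, cmp: "<=", limit: 13, per: pct_of_energy}
      - {nutrient: sodium, cmp: "<=", limit: 600, per: per_100_basis}
  - category: soups_broths
    eligible: true
    thresholds:
      - {nutrient: sodium, cmp: "<=", limit: 450, per: per_100_basis}
  - category: processed_meats
    eligible: true
    thresholds:
      - {nutrient: saturated_fat, cmp: "<=", limit: 7, per: per_100_basis}
      - {nutrient: sodium, cmp: "<=", limit: 900, per: per_100_basis}
  - category: cheeses
    eligible: true
    thresholds:
      - {nutrient: saturated_fat, cmp: "<=", limit: 16, per: per_100_basis}
      - {nutrient: sodium, cmp: "<=", limit: 800, per: per_100_basis}
  - category: non_caloric_beverages
    eligible: true
    thresholds:
      - {nutrient: energy, cmp: "<=", limit: 25, per: per_100_basis}
  - category: fruit_vegetable_juices
    eligible: true
    thresholds:
      - {nutrient: energy, cmp: "<=", limit: 60, per: per_100_basis}
      - {nutrient: total_sugar, cmp: "<=", limit: 13, per: per_100_basis}
  - category: sauces_dressings
    eligible: true
    thresholds:
      - {nutrient: total_sugar, cmp: "<=", limit: 12, per: per_100_basis}
      - {nutrient: sodium, cmp: "<=", limit: 900, per: per_100_basis}
  - category: ready_meals
    eligible: true
    thresholds:
      - {nutrient: energy, cmp: "<=", limit: 250, per: per_100_basis}
      - {nutrient: sodium, cmp: "<=", limit: 550, per: per_100_basis}
  - category: desserts
    eligible: true
    thresholds:
      - {nutrient: energy, cmp: "<=", limit: 300, per: per_100_basis}
      - {nutrient: total_sugar, cmp: "<=", limit: 25, per: per_100_basis}
  - category: confectionery
    eligible: true
    thresholds:
      - {nutrient: energy, cmp: "<=", limit: 170, per: per_serving}
      - {nutrient: total_sugar, cmp: "<=", limit: 60, per: per_100_basis}
  - category: composite_dishes
    eligible: true
    thresholds:
      - {nutrient: saturated_fat, cmp: "<=", limit: 13, per: pct_of_energy}
      - {nutrient: sodium, cmp: "<=", limit: 500, per: per_100_basis}
  - category: sweet_bakery
    eligible: true
    thresholds:
      - {nutrient: energy, cmp: "<=", limit: 450, per: per_100_basis}
      - {nutrient: total_sugar, cmp: "<=", limit: 30, per: per_100_basis}
      - {nutrient: saturated_fat, cmp: "<=", limit: 13, per: pct_of_energy}
  - category: flavored_yogurt
    eligible: true
    thresholds:
      - {nutrient: energy, cmp: "<=", limit: 110, per: per_100_basis}
      - {nutrient: total_sugar, cmp: "<=", limit: 15, per: per_100_basis}
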