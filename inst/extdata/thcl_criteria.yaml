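# Per-subgroup logo eligibility criteria. All conditions within a subgroup
# are conjunctive. `basis: per100` evaluates the standardized per-100 g/mL
# panel value; `basis: per_serving` rescales by the declared serving size
# before comparison against a per-serving threshold.
#
# Entries marked `anchored: true` carry thresholds fixed by published scheme
# documentation (sugar-sweetened beverage total sugar 6.0 g/100 mL; water-
# based sauce sodium band 5000-6000 mg/100 mL; instant noodle/porridge sodium
# 1000 mg per 50 g serving). The remaining entries are plausible placeholders
# so the registry covers every subgroup; all analytics are registry-agnostic.
version: thcl-criteria-0.1
subgroups:
  cakes:
    anchored: false
    conditions:
      - {nutrient: sugar_g,  cmp: le, threshold: 20,   basis: per100}
      - {nutrient: sat_fat_g, cmp: le, threshold: 10,  basis: per100}
  cookies_biscuits:
    anchored: false
    conditions:
      - {nutrient: sugar_g,  cmp: le, threshold: 20,   basis: per100}
      - {nutrient: sat_fat_g, cmp: le, threshold: 10,  basis: per100}
  sliced_bread:
    anchored: false
    conditions:
      - {nutrient: sodium_mg, cmp: le, threshold: 450, basis: per100}
      - {nutrient: sat_fat_g, cmp: le, threshold: 10,  basis: per100}
  breakfast_cereal:
    anchored: false
    conditions:
      - {nutrient: sugar_g,  cmp: le, threshold: 20,   basis: per100}
      - {nutrient: sat_fat_g, cmp: le, threshold: 10,  basis: per100}
  white_milk:
    anchored: false
    conditions:
      - {nutrient: sugar_g,  cmp: le, threshold: 5.5,  basis: per100}
      - {nutrient: sodium_mg, cmp: le, threshold: 120, basis: per100}
  flavored_milk:
    anchored: false
    conditions:
      - {nutrient: sugar_g,  cmp: le, threshold: 5.5,  basis: per100}
      - {nutrient: sodium_mg, cmp: le, threshold: 120, basis: per100}
  yogurt:
    anchored: false
    conditions:
      - {nutrient: sugar_g,  cmp: le, threshold: 10,   basis: per100}
      - {nutrient: sat_fat_g, cmp: le, threshold: 10,  basis: per100}
  dressing:
    anchored: false
    conditions:
      - {nutrient: sodium_mg, cmp: le, threshold: 1100, basis: per100}
      - {nutrient: sat_fat_g, cmp: le, threshold: 10,   basis: per100}
  mayonnaise:
    anchored: false
    conditions:
      - {nutrient: sodium_mg, cmp: le, threshold: 1100, basis: per100}
      - {nutrient: sat_fat_g, cmp: le, threshold: 10,   basis: per100}
  ice_cream:
    anchored: false
    conditions:
      - {nutrient: sugar_g,  cmp: le, threshold: 22,   basis: per100}
      - {nutrient: sat_fat_g, cmp: le, threshold: 10,  basis: per100}
  instant_noodles:
    anchored: true
    conditions:
      - {nutrient: sodium_mg, cmp: le, threshold: 1000, basis: per_serving, anchored: true}
      - {nutrient: sat_fat_g, cmp: le, threshold: 10,   basis: per100}
  instant_porridge:
    anchored: true
    conditions:
      - {nutrient: sodium_mg, cmp: le, threshold: 1000, basis: per_serving, anchored: true}
      - {nutrient: sat_fat_g, cmp: le, threshold: 10,   basis: per100}
  instant_tea:
    anchored: true
    conditions:
      - {nutrient: sugar_g,  cmp: le, threshold: 6.0,  basis: per100, anchored: true}
      - {nutrient: sodium_mg, cmp: le, threshold: 120, basis: per100}
  instant_coffee:
    anchored: true
    conditions:
      - {nutrient: sugar_g,  cmp: le, threshold: 6.0,  basis: per100, anchored: true}
      - {nutrient: sodium_mg, cmp: le, threshold: 120, basis: per100}
  malt_chocolate_drink:
    anchored: false
    conditions:
      - {nutrient: sugar_g,  cmp: le, threshold: 6.0,  basis: per100}
      - {nutrient: sodium_mg, cmp: le, threshold: 120, basis: per100}
  soy_milk:
    anchored: false
    conditions:
      - {nutrient: sugar_g,  cmp: le, threshold: 6.0,  basis: per100}
      - {nutrient: sodium_mg, cmp: le, threshold: 120, basis: per100}
  nut_cereal_milk:
    anchored: false
    conditions:
      - {nutrient: sugar_g,  cmp: le, threshold: 6.0,  basis: per100}
      - {nutrient: sodium_mg, cmp: le, threshold: 120, basis: per100}
  frozen_meal:
    anchored: false
    conditions:
      - {nutrient: sodium_mg, cmp: le, threshold: 600, basis: per100}
      - {nutrient: sat_fat_g, cmp: le, threshold: 10,  basis: per100}
  chilled_meal:
    anchored: false
    conditions:
      - {nutrient: sodium_mg, cmp: le, threshold: 600, basis: per100}
      - {nutrient: sat_fat_g, cmp: le, threshold: 10,  basis: per100}
  fish_sauce:
    anchored: true
    conditions:
      - {nutrient: sodium_mg, cmp: le, threshold: 6000, basis: per100, anchored: true}
  soy_sauce:
    anchored: true
    conditions:
      - {nutrient: sodium_mg, cmp: le, threshold: 5000, basis: per100, anchored: true}
  seasoning_powder:
    anchored: false
    conditions:
      - {nutrient: sodium_mg, cmp: le, threshold: 16000, basis: per100}
  small_meal:
    anchored: false
    conditions:
      - {nutrient: sodium_mg, cmp: le, threshold: 480, basis: per100}
      - {nutrient: sat_fat_g, cmp: le, threshold: 10,  basis: per100}
  potato_chips:
    anchored: false
    conditions:
      - {nutrient: sodium_mg, cmp: le, threshold: 500, basis: per100}
      - {nutrient: sat_fat_g, cmp: le, threshold: 10,  basis: per100}
  extruded_snack:
    anchored: false
    conditions:
      - {nutrient: sodium_mg, cmp: le, threshold: 500, basis: per100}
      - {nutrient: sat_fat_g, cmp: le, threshold: 10,  basis: per100}
  meat_snack:
    anchored: false
    conditions:
      - {nutrient: sodium_mg, cmp: le, threshold: 500, basis: per100}
      - {nutrient: sat_fat_g, cmp: le, threshold: 10,  basis: per100}
  nuts_seeds:
    anchored: false
    conditions:
      - {nutrient: sodium_mg, cmp: le, threshold: 240, basis: per100}
  bean_snack:
    anchored: false
    conditions:
      - {nutrient: sodium_mg, cmp: le, threshold: 240, basis: per100}
  wet_soup:
    anchored: false
    conditions:
      - {nutrient: sodium_mg, cmp: le, threshold: 340, basis: per100}
      - {nutrient: sat_fat_g, cmp: le, threshold: 10,  basis: per100}
  instant_soup:
    anchored: false
    conditions:
      - {nutrient: sodium_mg, cmp: le, threshold: 1500, basis: per100}
      - {nutrient: sat_fat_g, cmp: le, threshold: 10,   basis: per100}
  carbonated_soft_drink:
    anchored: true
    conditions:
      - {nutrient: sugar_g,  cmp: le, threshold: 6.0,  basis: per100, anchored: true}
      - {nutrient: sodium_mg, cmp: le, threshold: 120, basis: per100}
  functional_drink:
    anchored: true
    conditions:
      - {nutrient: sugar_g,  cmp: le, threshold: 6.0,  basis: per100, anchored: true}
      - {nutrient: sodium_mg, cmp: le, threshold: 120, basis: per100}
  fruit_juice:
    anchored: true
    conditions:
      - {nutrient: sugar_g,  cmp: le, threshold: 6.0,  basis: per100, anchored: true}
      - {nutrient: sodium_mg, cmp: le, threshold: 120, basis: per100}
  vegetable_juice:
    anchored: true
    conditions:
      - {nutrient: sugar_g,  cmp: le, threshold: 6.0,  basis: per100, anchored: true}
      - {nutrient: sodium_mg, cmp: le, threshold: 120, basis: per100}
  juice_drink:
    anchored: true
    conditions:
      - {nutrient: sugar_g,  cmp: le, threshold: 6.0,  basis: per100, anchored: true}
      - {nutrient: sodium_mg, cmp: le, threshold: 120, basis: per100}
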