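# Health-Star-Rating-style nutrient profiling point tables (versioned asset).
#
# Band vectors list the LOWER edge of each successive point band; bands are
# closed on the lower edge, open on the upper, and saturate at the top band.
# The banding follows the published NPSC pattern: one baseline point per
# 335 kJ energy (finer 67 kJ steps for beverages), per ~1 g saturated fat,
# ~4.5 g total sugars, and 90 mg sodium, with extended bands for
# energy-dense foods; modifying points for FVNL%, protein, and fiber.
# Star matrices map the final score (baseline - modifying) to half-star
# ratings per category; they are monotone non-increasing in score.
#
# The asset is editable and version-stamped; no claim of regulatory
# equivalence with any official calculator is made.
version: hsr-tables-7.0
baseline:
  energy_kj:
    food:     [335, 670, 1005, 1340, 1675, 2010, 2345, 2680, 3015, 3350, 3685]
    beverage: [67, 134, 201, 268, 335, 402, 469, 536, 603, 670, 737]
  sat_fat_g: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10,
              11.2, 12.5, 13.9, 15.5, 17.3, 19.3, 21.6, 24.1, 26.9, 30,
              33.5, 37.4, 41.7, 46.6, 52, 58, 64.7, 72.3, 80.6, 90]
  sugar_g:   [5, 8.9, 13.4, 17.9, 22.4, 26.8, 31.3, 35.8, 40.3, 44.7,
              49.2, 53.6, 58.1, 62.6, 67, 71.5, 76, 80.4, 84.9, 89.4]
  sodium_mg: [90, 180, 270, 360, 450, 540, 630, 720, 810, 900,
              990, 1080, 1170, 1260, 1350, 1440, 1530, 1620, 1710, 1800,
              1890, 1980, 2070, 2160, 2250, 2340, 2430, 2520, 2610, 2700]
modifying:
  fvnl_pct:  [25, 43, 52, 63, 67, 80, 90, 96]
  protein_g: [1.6, 3.2, 4.8, 6.4, 8.0, 9.6, 11.2, 12.8, 14.4, 16.0,
              17.6, 19.2, 20.8, 22.4, 24.0]
  fiber_g:   [0.9, 1.8, 2.7, 3.6, 4.5, 5.4, 6.3, 7.2, 8.1, 9.0,
              9.9, 10.8, 11.7, 12.6, 13.5]
  # combined FVNL% = 100 * (nonconc + w * conc) / (100 + (w - 1) * conc)
  conc_weight: 2
protein_cap:
  # protein points count only if baseline points are below the threshold or
  # FVNL points reach v_required
  baseline_threshold: 13
  v_required: 5
star_matrix:
  # ascending final-score cutoffs; stars = 5.0 - 0.5 * #(cutoffs <= score)
  "1":  [-1, 0, 1, 2, 3, 4, 5, 6, 7]
  "1D": [-2, 0, 2, 4, 6, 8, 10, 12, 14]
  "2":  [-11, -6, -2, 2, 6, 10, 15, 20, 25]
  "2D": [-6, -2, 2, 6, 10, 14, 18, 22, 26]
grade_map:
  # half-star rating -> 5-grade letter (A healthiest)
  A: [4.5, 5.0]
  B: [3.0, 3.5, 4.0]
  C: [2.0, 2.5]
  D: [1.0, 1.5]
  E: [0.5]
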