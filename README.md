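# fopnl

Surveillance tooling for voluntary **front-of-pack nutrition labeling
(FOPNL)** uptake in packaged-food launch databases, built around Thailand's
**Healthier Choice Logo (THCL)** endorsement scheme.

Public-health teams monitoring an endorsement logo face the same questions
every year: of the products newly launched in the market, how many *could*
carry the logo under their food category's nutrient criteria, how many *do*,
and where is that share heading? `fopnl` turns a table of product launch
records — barcode, release year, category codes, ingredient list, the
back-of-pack nutrition information panel (NIP), and a logo-presence flag —
into those answers.

## What the pipeline does

1. **Standardize** NIPs to per 100 g/mL with energy in kJ
   (kcal × 4.184), resolve "less than" declarations to their closest whole
   number, convert calcium/iron %RDA to mg, and deduplicate by barcode
   (each package size is an individual product).
2. **Categorize** database minor categories into 35 scheme subgroups and 18
   reporting groups, mark scheme-scope exclusions (drinking water, vinegar,
   infant foods, medical foods, supplements, ...), and apply each
   subgroup's criteria start year (e.g. bakery/bread/breakfast cereal count
   only from 2019).
3. **Impute** fiber (subgroup mean of non-zero declarations, or
   nearest-energy donor matching) and fruit/vegetable/nut/legume content
   (**FVNL**, a four-band decision tree over ingredient-list position) where
   labels do not declare them.
4. **Score** healthfulness with a table-driven **Health Star Rating (HSR)**
   engine — baseline points for energy, saturated fat, total sugars and
   sodium minus modifying points for FVNL, protein and fiber, mapped to
   0.5–5.0 stars in half-star steps — and **classify** logo eligibility with
   a per-subgroup YAML criteria registry (conjunctive `nutrient ≤/≥
   threshold` conditions per 100 g/mL or per serving).
5. **Analyze** uptake. Per year, with `n` labeled products:

   - uptake per total products = n / N_total
   - uptake per eligible products = n / N_eligible

   and the closed-form least-squares trend `y = a + bX` (X = 1, 2, … from
   the first fit year),

   ```
   b = (n Σty − Σt Σy) / (n Σt² − (Σt)²),   a = (Σy − b Σt) / n
   ```

   with a t-based 95% slope CI, R², linear projections (clamped to [0, 1]
   for display), chi-square comparisons across strata, and Table-style
   stratified reports by reporting group, HSR value, or manufacturer
   (makers with <5 labeled products fold into "All other companies").

Because the commercial launch databases this is designed for are
proprietary, the package ships a **synthetic generator**
(`default_study_scenario()`, `generate_products()`) calibrated against the
published five-year Thai surveillance counts (~27% of launches eligible,
10.7% labeled overall, 39.5% of eligible labeled, eligible-uptake trend
≈ 0.10/yr), with ground-truth annotations for closed-loop testing.

## Worked example

```r
library(fopnl)

scenario <- default_study_scenario()      # ~7767 launches, 2017-2021
batch    <- generate_products(scenario, seed = 1)
ann      <- annotate_batch(batch)         # categorize, impute, score, classify

mean(ann$eligible)                        # 0.2688
series <- uptake_series(ann)
fit <- fit_linear_trend(series$year, series$uptake_eligible)
fit
#> <fopnl_trend> y = 0.1110 + 0.0945 X (X=1 at 2017), R^2 = 0.9950,
#>               slope 95% CI [0.0822, 0.1068]
project_uptake(fit, 2027)[7, ]
#> # A tibble: 1 x 4
#>    year     x predicted clamped
#>   <int> <dbl>     <dbl>   <dbl>
#> 1  2027    11      1.15       1
```

Reading: about 26.9% of the synthetic launches meet their subgroup's
criteria; the share of eligible products that carry the logo grows by about
9.5 percentage points per year, and the linear trend crosses 100% (clamped)
before 2027 — the pattern the scenario is calibrated to emulate. Reports:

```r
build_report(ann, by = "reporting_group")   # Table-1-style rows
build_report(ann, by = "manufacturer")      # Table-2-style rows
plot_uptake_trend(series, horizon_year = 2027)
```

Real data enter through `read_records("launches.csv", dialect = ...)`; all
assets (category map, criteria registry, HSR tables, lexicons) are editable
YAML under `inst/extdata/`.

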