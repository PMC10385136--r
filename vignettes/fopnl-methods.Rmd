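---
title: "Methods: measuring endorsement-logo uptake in launch databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring endorsement-logo uptake in launch databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fopnl)
```

`fopnl` estimates the uptake of a voluntary front-of-pack endorsement logo
— modelled on Thailand's Healthier Choice Logo (THCL) — from serial
cross-sections of newly launched packaged foods. This vignette documents
the statistical model, the imputation and scoring procedures, the design
choices that were genuinely open, and what the synthetic test bed does and
does not establish about real data.

## The measurement model

Each launch record is one product (one barcode; package sizes are distinct
products) with a release year, category codes, an ingredient list in
descending predominance order, a nutrition information panel (NIP), and a
logo-presence flag. For year $t$ within a category's *eligibility window*
(the years since its criteria were published), we track three counts:
launches $N_t$, launches meeting their subgroup's criteria $E_t$
("eligible"), and eligible launches displaying the logo $n_t$. The two
uptake measures are $n_t/N_t$ and $n_t/E_t$.

Uptake trends are fitted by closed-form least squares of the yearly
proportion on the period index $X = 1, 2, \dots$ counted from the first
fit year:

$$b = \frac{n\sum t y - \sum t \sum y}{n \sum t^2 - (\sum t)^2},
\qquad a = \frac{\sum y - b \sum t}{n}.$$

The slope's 95% CI uses the usual OLS standard error with a $t$ quantile
at $n-2$ degrees of freedom; the published intervals this mirrors do not
state their method, so the $t$-based CI is our documented choice.
Projections extrapolate $a + bX$ per year and are clamped to $[0, 1]$ for
display (the unclamped value is retained). The $X{=}1$ origin convention
is itself checked against a published anchor: the five-year overall-uptake
fit $y = 0.0301X - 0.0199$ evaluated at $X = 11$ (2027) gives 31.1%,
within the published "approximately 32.1%" once that report's own rounding
is allowed for — calendar-year encodings do not reproduce it. Differences
in uptake between strata use Pearson's chi-square without continuity
correction on the 2×k labeled/not-labeled table ($df = k-1$); expected
cells below 1 attach a warning annotation rather than an error.

Report percentages round half-up to one decimal, matching the display
convention of published surveillance tables. While verifying that every
published count pair reproduces its printed percentage, two cells turned
out to be typos in the source table (2/11 prints 18.1 instead of 18.2;
195/332 prints 57.8 instead of 58.7); the shipped fixture flags them and
the tests assert the recomputed values.

## Panel standardization

NIPs arrive per serving and/or per 100 g/mL, energy in kcal or kJ,
calcium/iron possibly as %RDA. Standardization rescales linearly to per
100 basis-units (beverages per 100 mL, foods per 100 g), converts energy
at 4.184 kJ/kcal, and converts %RDA to mg with configurable reference
values (defaults: calcium 800 mg, iron 15 mg — Thai RDI-style references;
the conversion is specified by the scheme but the constants are not, so
they live in config). Values declared "less than" are adjusted to the
whole number closest to the bound; the canonical example `<1.0 g` → 1.0 g
is consistent with both nearest and ceiling rounding, so the rule is
configurable with `nearest` (half-up) as the less aggressive default.
Records without a usable as-prepared NIP are excluded with a recorded
reason, never silently dropped. Soft inconsistencies a label can legally
carry (saturated fat above total fat, sugars above carbohydrate) are
flagged, not rejected.

## Categorization

A YAML crosswalk maps launch-database minor categories to 35 scheme
subgroups and 18 reporting groups, with a criteria start year, panel
basis, and an HSR category hint per subgroup. Only the edges the source
documentation fixes are marked `anchored` (the 18 group names, the
RTD-tea→instant-tea merge, beverages/dairy/snacks starting 2016, ice
cream 2017, bakery/bread/breakfast-cereal 2019); the remaining roster is
interpolated to a realistic shape and is user-editable, because the full
official appendix is not reproduced here. The window test is inclusive at
the start year (adoption-year launches count). Unmapped minors produce a
mapping-gap report rather than a guess, and categorization depends only
on category codes and year — never on nutrients.

## Fiber and FVNL imputation

Thai NIPs need not declare fiber or fruit/vegetable/nut/legume (FVNL)
content, so both are estimated from the ingredient list when absent.

*Fiber.* Products listing a fiber-source ingredient (inulin, psyllium,
pectin, fructooligosaccharides, brans, whole grains, ...) but no declared
value receive, in subgroups with a homogeneous product range (popcorn-like
snacks, dressings, wet soups), the mean of the subgroup's non-zero
declared values; in heterogeneous subgroups, the declared value of the
most similar donor. "Similar" is operationalized as nearest energy per
100 basis-units with ties broken by lower barcode — the source procedure
says only "matched to similar products", and energy is the least
category-specific proxy. Products with neither a declaration nor a fiber
source get fiber 0 rather than exclusion (implied by the workflow, not
stated). Imputation never alters a declared value.

*FVNL.* A four-band decision tree over ingredient position assigns
concentrated/non-concentrated percentage bands: sole weight-contributing
ingredient → 100/100; first ingredient with only minor additives beside it
→ ≥67 / >80; within the first three (concentrated) or two
(non-concentrated) ingredients → ≥25 / >40; otherwise <25 / ≤40.
"Does not substantially contribute to weight" has no quantitative
threshold in the source, so it is operationalized as a configurable
minor-additive lexicon (salt, flavouring, acidity regulators, ...). The
band representative defaults to the lower bound — conservative for the
downstream modifying points — with a midpoint option. Exhaustive
enumeration over flag patterns (lists up to length 5) verifies exactly one
rule fires for every configuration. The cited external decision tree may
contain finer rules; only the four-band summary is implemented.

## HSR scoring

The Health Star Rating engine is entirely table-driven
(`hsr_tables_v7.yaml`, version-stamped and carried into every result):
baseline points for energy (finer bands for beverages), saturated fat,
total sugars and sodium; modifying points for combined FVNL%, protein and
fiber; final score = baseline − modifying; per-category monotone matrices
map scores to 0.5–5.0 stars in half-star steps. Bands are closed on the
lower edge and open above (the published phrasing varies; one convention
is fixed and tested at every boundary) and saturate at the top band.
Concentrated FVNL counts double through
$100\,(N + 2C)/(100 + C)$, so a pure concentrate still reaches 100%.
Protein points count only while baseline points are below 13 or FVNL
points reach 5 (the cap rule, parameters in config). Categories are 1
(non-dairy beverage), 1D (dairy beverage), 2 (non-dairy food), 2D (dairy
food); oils/spreads- and cheese-style products are explicitly unscored
and excluded from scoring, matching the surveillance scope. Category
routing uses the subgroup hint first and a basis/dairy fallback second;
no free-text product-name classification is attempted. The shipped tables
follow the published banding pattern (one point per 335 kJ, ~1 g
saturated fat, ~4.5 g sugars, 90 mg sodium, with extended bands for
energy-dense foods); they are an editable asset and no claim of
regulatory equivalence with the official calculator is made — the tested
guarantees are monotonicity, the score identity, and the half-star range.
The 0.5–5.0 scale also collapses to a five-letter grade (A: 4.5–5.0;
B: 3.0–4.0; C: 2.0–2.5; D: 1.0–1.5; E: 0.5). The published two-anchor
correspondence (4.5–5 ↔ A, 3–3.5 ↔ B) leaves 4.0 unassigned; it is
grouped with B so the grades partition the scale, and the map is config.

## Eligibility rules engine

Each subgroup's criteria are a conjunctive list of `nutrient ≤/≥
threshold` conditions on the standardized panel, per 100 g/mL or per
declared serving. Three thresholds are anchored by the source (total
sugar ≤ 6.0 g/100 mL for sugar-sweetened beverages; sodium ≤ 5000–6000
mg/100 mL for water-based sauces, modelled as soy- and fish-sauce
subtypes so both band endpoints are representable; sodium ≤ 1000 mg per
50 g serving for instant noodles/porridge); the rest of the registry is
plausible placeholders, each tagged, and all analytics are
registry-agnostic. Missing criteria, nutrients, or serving sizes fail
closed with an explicit flag. Boundary behaviour is inclusive (a product
exactly at a ≤ threshold is eligible), and tightening any threshold can
only shrink the eligible set — both property-tested.

## The synthetic test bed

The generator emulates the structure of a commercial launch database; its
defaults are calibrated backwards from the published five-year counts,
which ship as a plain-text fixture:

- launch counts per reporting group proportional to the published group
  totals (7767 in-window launches over 2017–2021, late-start groups only
  from 2019), split evenly over subgroups and window years;
- for each subgroup, the *binding* (first) criteria condition gets a
  log-normal nutrient distribution (σ = 0.5 on the log scale) whose mass
  below the threshold equals the group's published eligible share, so the
  expected overall eligible share is 27.0% by construction; companion
  conditions are satisfied with probability ≈ 1 under the default
  distributions;
- display is drawn conditional on true eligibility with a per-group
  linear-in-year curve centred on the group's published eligible-uptake
  and global slope 0.1024/yr, shrunk per group just enough to stay in
  [0, 1] (this avoids clamp bias, so group means land exactly on their
  calibration targets and the expected overall uptake is 10.7%/39.5%);
  P(display | ineligible) is 0 by default, with an anomaly-rate knob to
  exercise the display-consistency tags;
- manufacturers come from a Zipf firm-size model (1875 firms, exponent
  1.1) — deliberately coarse; firm-level adoption heterogeneity is not
  modelled, so manufacturer-table shapes are structural, not calibrated;
- fiber declarations are missing with probability 0.25 in solid foods to
  exercise the imputation path; FVNL is always derived from ingredients.

Ground-truth eligibility is computed inside the generator by a naive
per-condition loop, independent of the vectorized rules engine; a
closed-loop test requires 100% agreement. The scenario also computes its
expected pooled eligible-uptake curve and that curve's OLS slope (~0.094:
slightly below the per-group 0.1024 because low-uptake groups get
shrunken slopes and late-start groups shift the composition). That
expected slope is the recovery truth: over 200 seeded full-size
replicates, the fitted slope's 95% CI covers it in ≈95% of runs, and each
replicate's eligible share stays within 2 points of 27%.

What passing these tests shows: the pipeline's arithmetic, classification
logic and trend machinery are correct, and the estimator recovers known
parameters under realistic sample sizes. What it does not show: anything
about real label-reading error, re-labeling lag, true nutrient
distributions (real label data are messier than independent log-normals),
or the actual criteria thresholds beyond the three anchored ones.

## Numerical choices and degenerate inputs

- Panel comparisons use 1e-9 relative tolerance; trend-fit equivalence to
  a generic least-squares oracle is tested at 1e-10.
- Constant uptake series fit slope 0 with undefined R² and are flagged
  degenerate; fits need at least two distinct years.
- Zero denominators report `N/A`, never 0 or an error.
- Duplicate barcodes keep the first-seen record (no tie-break is
  specified by the source); the removed count is reported.
- Problem sizes in the test suite: property sweeps use 1000 random
  panels/series; recovery uses 200 replicates of the full ~7767-launch
  scenario; unit tests run on a 10%-scale scenario.

## Known limitations

- The category roster, most criteria thresholds, and most start years are
  interpolated placeholders (tagged in the YAML); real deployments should
  replace them with the official appendix.
- The HSR tables are an HSR-style asset, not the official calculator.
- Launch counts measure product-innovation activity, not market share or
  retention; no sales weighting is attempted.
- One published total (2139 eligible products) conflicts with the
  consistent 2097 elsewhere in the same source; the fixture uses 2097.
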