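---
title: "Simulating front-of-package food replacement: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating front-of-package food replacement: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fopsim)
```

## The question the package answers

Front-of-package (FOP) nutrition logos mark processed foods that meet
category-specific nutrient criteria. A natural policy question is: *if
consumers replaced the non-compliant processed foods in their current diet
with compliant foods of the same category, how would population energy and
nutrient intake change?* `fopsim` implements that substitution simulation
for 24-hour dietary recall (24HR) data collected under a complex survey
design, and reports the change in survey-weighted medians of energy,
saturated fat, trans fat, total sugar, sodium and fiber intake.

Three scenarios are compared:

1. **Scenario 1** — observed intake, untouched.
2. **Scenario 2** — every consumed non-compliant processed food is swapped
   for a compliant food of the same category, keeping the consumed amount.
   Foods with no compliant same-category candidate are left unreplaced.
3. **Scenario 3** — as scenario 2, but the consumed amount is multiplied by
   the ratio of energy densities (original / replacement), so each replaced
   entry delivers exactly the energy it did before. For example, a
   446.86 kcal/100 g cereal bar replaced by a 290.5 kcal/100 g bar gets the
   factor 446.86 / 290.5 = 1.54: 100 g of the original becomes 154 g of the
   replacement. Categories where rescaling would imply implausible portions
   — sugar-sweetened beverages, bakery, dairy — are exempt: they are
   replaced but keep the scenario-2 amount.

A restricted variant (`run_restricted_replacement()`) replaces foods in a
chosen category subset only, e.g. sugar-sweetened beverages alone.

## Classification model

A criteria set (`criteria_set()`, `load_criteria()`) is a named collection
of per-category rules. Each rule is a list of thresholds
`(nutrient, comparator, limit, denominator)` plus an eligibility flag;
ineligible categories (e.g. sugar-based products under regulatory-style
criteria) can never carry the logo. Denominators:

| denominator | observed value |
|---|---|
| `per_100_basis` | the per-100 g/mL profile value |
| `per_serving` | profile value × serving size / 100 |
| `pct_of_energy` | 100 × *k* × grams / energy kcal, *k* = 9 kcal/g for fats, 4 kcal/g for sugars |
| `pct_of_total_fat` | 100 × grams / total-fat grams |

Design choices worth knowing:

* **Comparators are inclusive** (≤ / ≥); a food exactly at its limit
  complies. Fiber is the only nutrient that takes ≥ ("more is better").
* **Energy conversion uses Atwater-type factors** (9 and 4 kcal/g) for
  percent-of-energy thresholds.
* **Missing data fail conservatively.** A threshold on a missing nutrient,
  a per-serving rule on a food without a serving size, or a percentage
  denominator with zero energy/total fat all count as failures with a
  recorded reason. A food with incomplete composition therefore never
  becomes a replacement candidate, but classification does not crash.
* Two illustrative criteria configurations ship under
  `inst/extdata/`: a 19-category committee style set whose sugar rules
  target *added* sugar, and a 26-category regulatory-style set targeting
  *total* sugar with sugar-based categories ineligible. Their numeric
  limits are demonstrations of the structure, not published cut-offs,
  which is why every quantitative test in the package runs on criteria
  generated together with synthetic foods.

## Replacement map

For each non-compliant processed food the candidate set is every compliant
processed food of the same category; if empty, the food is unreplaced. The
default rule picks the candidate with the nearest energy density, ties
broken by lexicographic food id. Rationale: "similar food" is
underdetermined; nearest energy density minimizes the scenario-3
correction factor and is fully deterministic. The rule is pluggable
(`candidate_rule` may be a function) so a nutrient-distance alternative can
be swapped in. The map is global — one replacement per product, not per
recall entry. A zero or missing energy density on either side of a pair
makes the correction factor undefined; such pairs fall back to factor 1
with a warning.

## Participant exclusions

`apply_exclusions()` reproduces the screening conventions of adult dietary
surveys: keep ages 20–59, drop pregnant/lactating women, drop aberrant BMI
(outside 10–58 kg/m²), and drop implausible energy reporters outside the
unweighted mean ± 3 SD of daily energy. The energy screen is computed
**once** over the pool surviving the earlier filters and is not iterated;
iterating would change the sample in ways no convention specifies. A
person failing several filters is audited once, under the first applicable
reason in the fixed order age → pregnancy → BMI → energy → missing data,
so audits are reproducible. Persons with missing age or BMI are excluded
as `missing_data` and are left out of the energy mean/SD pool.

## Survey-weighted statistics

**Quantiles.** `weighted_quantile()` uses the left-continuous
cumulative-weight definition: the smallest value whose normalized
cumulative weight reaches *p*, averaging the two adjacent order statistics
when the cumulative weight hits *p* exactly. With equal weights this is
R's `quantile(type = 2)` for every *p*. We chose this step-function
definition (rather than a smoothly interpolating one) because expansion
weights can be extremely unequal: a point carrying dominant weight should
absorb the quantile rather than be averaged away with a far-off neighbor.

**Percent change** between scenarios is always computed from the
*unrounded* weighted medians (`100 × (after − before) / before`) and only
rounded for display — recomputing changes from a rounded table will
generally not reproduce them to the printed decimal.

**Contrasts.** Following common practice for skewed intake, scenario
contrasts fit a weighted linear model of `log(intake + δ)` on a scenario
indicator over the stacked person×scenario records, with a cluster-robust
sandwich variance at the PSU-within-stratum level and a t reference with
(clusters − 1) degrees of freedom. Because every person appears in both
scenarios and persons nest in PSUs, the clustering also absorbs the
within-person pairing. This is a desk-scale stand-in for full
Taylor-linearized survey machinery and is deliberately swappable. The
offset δ is half the smallest positive observed value of the nutrient
across both scenarios (trans-fat intake contains exact zeros); δ is
reported in the output. The offset slightly compresses log-scale effect
estimates, which the tests account for. Significance is two-sided at 0.05
with no multiplicity correction. When the two intake vectors are
numerically identical the contrast short-circuits to estimate 0, p = 1,
because the sandwich t-ratio would be 0/0 noise.

## The synthetic-data generator

Real 24HR microdata from national surveys are restricted, so the package
ships a generator (`generate_survey()`) whose output has analytically
known ground truth. It emulates:

* daily energy log-normal with median 1905 kcal and log-SD 0.43 (p25–p75
  roughly 1380–2480 kcal), matching the scale of adult national surveys;
* a food supply of 12 categories — 3 unprocessed staple categories plus 9
  processed ones (sugar-sweetened beverages carrying the largest single
  consumption share) with 8 foods each;
* planted compliance: compliant foods are formulated with −15% energy
  density and, per kcal, −40% saturated fat, −35% trans fat, −50% sugar,
  −25% sodium and +30% fiber relative to non-compliant foods of the same
  category; 60% of processed-category consumption falls on non-compliant
  foods; 75% of processed categories contain a compliant candidate;
* a stratified design (8 strata × 6 PSUs) with log-normal expansion
  weights, and planted exclusion cases (5 pregnant, 2 aberrant-BMI, 3
  energy outliers at 6× the median energy by default).

Three deliberate stylizations make the planted ground truth exact rather
than approximate; each trades realism for testability and is the reason
pipeline tests at ±2 percentage points are meaningful:

1. **Compliance labels are enforced by rejection sampling** against the
   generated criteria set (thresholds placed 3 noise-SDs beyond the
   compliant anchors), so every planted label classifies exactly as
   planted.
2. **Diet composition is stable across persons**: each person consumes
   every category at the population share times log-normal portion noise,
   and the non-compliant fraction within a category enters as an amount
   fraction, not a per-entry coin flip. Without this, the replaced share
   of a nutrient is lumpy across persons and the *median*-based pipeline
   estimate drifts systematically from the *mean*-based closed form. Real
   surveys have exactly that between-person heterogeneity; passing tests
   on generated data therefore validate the pipeline arithmetic, not the
   median-vs-mean behavior of any real population.
3. **Energy-density noise within a category is tight** (log-SD 0.03 vs
   0.05 for nutrients), because within a category, brand-to-brand energy
   density varies much less than individual nutrients; it also keeps the
   nearest-energy-density candidate rule nearly neutral with respect to
   the planted per-kcal reductions. The residual selection effect — the
   rule effectively picks the highest-energy compliant candidate, an
   order-statistic of the energy noise — is modeled in the closed form
   (`expected_change()`) together with the log-normal ratio terms.
4. **Regular energy targets are drawn from the log-normal truncated at
   ±1.8 log-SD**, so the only persons outside the ±3 SD energy screen are
   the planted outliers and exclusion ground truth is a set equality, not
   a probabilistic statement.

`expected_change()` gives the closed-form expected percent change of
population intake under scenario 2 or 3 (optionally restricted to chosen
categories) from the planted shares and reduction fractions. Under
scenario 3 a replaced entry conserves energy, so a nutrient's replaced
portion scales by `1 − r` (its per-kcal reduction); under scenario 2 and
in exempt categories the amount is kept, so it scales by the per-100
ratio `(1 − r)(1 − r_energy)`.

## Problem sizes and numerical choices

The test suite validates parameter recovery on surveys of 2000
participants across 10 generator seeds (the scale at which the ±2
percentage-point tolerance is assessed, comparing the 10-seed mean
estimate with the closed form), checks classification and weighted
quantiles against independent brute-force implementations on 200 random
fixtures of up to 50 foods / 25 observations, and verifies the ~5%
type-I error of the scenario contrast over 1000 simulated null surveys of
240 persons in 48 PSUs. Quantile ties use a 10⁻¹² tolerance on cumulative
weights; scenario-3 energy conservation is exact to 10⁻⁹ relative error
by construction.

## Known limitations

* Total replacement: every consumer of a replaced food switches; no
  partial or probabilistic substitution, and no behavioral response.
* One 24HR per person; no usual-intake (measurement-error) modeling.
* The cluster-robust contrast is not a replicate-weight or fully
  Taylor-linearized survey variance.
* The shipped criteria configurations are structural illustrations; real
  policy analysis requires the authority's published cut-offs in the same
  YAML format.
* The generator does not mimic any real food-frequency distribution; see
  the stylizations above for what passing tests do and do not establish.
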