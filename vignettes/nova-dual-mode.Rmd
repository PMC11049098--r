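---
title: "Dual-mode NOVA classification and Nutri-Score profiling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-mode NOVA classification and Nutri-Score profiling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(novascore)
```

## The problem

The NOVA taxonomy sorts foods into four groups by the degree and purpose of
their processing: unprocessed or minimally processed foods (NOVA1), processed
culinary ingredients (NOVA2), processed foods (NOVA3), and ultra-processed
foods (NOVA4). How a food is assigned depends critically on what the assessor
can see. Generic food composition databases expose only a food's name;
branded databases built from on-package data also expose the full ingredient
list, where the markers of ultra-processing (additives, industrial
sweeteners, protein isolates, and so on) actually live.

`novascore` implements both assessment modes as explicit, reproducible rule
systems, a nutrient-profiling engine (FSAm-NPS score and five-level
Nutri-Score grade), and the comparison layer that quantifies how much the two
modes disagree and what that disagreement means nutritionally. Because
branded databases are typically proprietary, the package also ships a
seeded synthetic generator that emulates the statistical structure of such a
database with known ground truth.

## Name-based classification (the "generic" mode)

Product names are normalized (lowercasing, punctuation stripping, folding of
common spelling variants such as yoghurt/yogurt and flavour/flavor; the long
descriptive name, when present, is concatenated with the product name) and
matched against a lexicon of indicative terms shipped as a plain CSV. Each
rule carries `required_terms` (all must match), `any_terms` (at least one
must match), and `forbidden_terms` (none may match); matching is whole-word
after normalization, with no stemming, favouring reproducibility over
recall.

Rules are evaluated in precedence order NOVA4 → NOVA3 → NOVA2 → NOVA1, and
the first matching rule wins. The order matters because minimally processed
entries are qualified negatively ("yogurt *without sugar*", "juices *with no
added sugar*"): the more-processed patterns must be tested first, and the
forbidden-term lists implement the qualifiers. A name matching no rule is
reported `unclassified` rather than silently defaulted — human compilers
classify everything by judgment, which a rule system should not pretend to
replicate.

The packaged lexicon transcribes the published indicative-term table and
nothing more. Notably that table has no entry that captures plain cheese
(traditionally NOVA3); names without a recognizable term simply come back
unclassified, and users can extend the CSV.

## Ingredient-based classification (the "branded" mode)

Ingredient lists are tokenized on commas and semicolons; parenthetical
sub-ingredients are recursively extracted as additional tokens; percentage
annotations are stripped. Tokens are screened against a two-tier marker
lexicon:

* **Tier 1 — culinary ingredients**: salt, sugar, honey, named oils, butter,
  starch, vinegar. Adding these to a minimally processed base is the
  definition of a *processed* food, so a tier-1 hit promotes a NOVA1 base to
  NOVA3.
* **Tier 2 — ultra-processing markers**: non-caloric sweeteners, industrial
  caloric sweeteners (glucose syrup, invert sugar, maltodextrin, ...),
  protein isolates and concentrates, added flavors and flavor enhancers,
  emulsifiers, gums and other thickeners, preservatives and antioxidants,
  industrial nutrient forms, and any E-number token (`e` + 3–4 digits,
  matched by pattern without a whitelist). Any tier-2 hit makes the food
  NOVA4.

The cascade is monotone: the ingredient-based class is never lower than the
name-based class; NOVA1 → NOVA3 is the only promotion that does not end in
NOVA4; and a name-based NOVA4 is sticky (packaged bread stays NOVA4 whatever
its list says). Records without an ingredient list cannot be assessed in
this mode and are excluded, mirroring how such records must be dropped from
a branded-database analysis.

Decisions that were genuinely open and how we resolved them: plain salt is
tier 1 while named sodium salts (nitrite, benzoate, phosphate, ...) are
tier 2, since the latter are additives rather than kitchen ingredients;
water, yeast and starter cultures are neutral (present in traditional
processing); iron and folic acid are exempt from the tier-2
nutrient-form class in the milled-grain category, where fortified flours
remain minimally processed by definition. All of this is data, not code:
the marker lexicon is a CSV with `tier`, `class`, `pattern` and
`exempt_category` columns.

## FSAm-NPS score and Nutri-Score grade

Four "negative" nutrients — energy (kJ), total sugars (g), saturated fat
(g), sodium (mg), all per 100 g or 100 mL as declared — score 0–10 points
each for increasing content; three "positive" components — protein (g),
fiber (g), and the fruit/vegetable/pulse/nut/oil share FV% — score 0–5. The
FSAm-NPS score is the negative total minus the positive total, an integer in
[−15, 40]; lower is healthier. The point thresholds (packaged as CSV, strict
"greater than" bands) are the published 2015/2017 FSAm-NPS tables: energy
at 335, 670, ..., 3350 kJ; sugars at 4.5, 9, ..., 45 g; saturated fat at
1–10 g; sodium at 90–900 mg; protein at 1.6, 3.2, 4.8, 6.4, 8.0 g; fiber at
0.9, 1.9, 2.8, 3.7, 4.7 g; FV% at 40/60/80 mapping to 1/2/5 points.

Two presets are provided because the analysis this package operationalizes
describes the combination step only as a simple subtraction:

* `"paper"` (default): plain subtraction, food scales for every product.
* `"fsam2017_full"`: the full published algorithm — beverage-specific energy,
  sugar and FV scales, and the protein cap (protein not counted when the
  negative total reaches 11, unless FV points are maximal or the food is a
  cheese).

Grades: solids get A up to −1, B for 0–2, C for 3–10, D for 11–18, E for
19–40; beverages are graded more strictly (B up to 1, C 2–5, D 6–9, E
10–40) and never receive A; waters are always A. The solid A band is
implemented as *score ≤ −1* rather than the sometimes-quoted "−5 to −1":
legume products average scores well below −5 and are uncontroversially grade
A, so the literal lower bound cannot be right. Grade bands partition the
whole score range for every physical state (a tested invariant).

Missing-data policy: a record missing any negative nutrient cannot be scored
and is excluded (`excluded_missing_negative`); missing positive components
are imputed with zero and recorded per record in `imputed_positives`.
Missingness is preserved at load time — absent cells are `NA`, never zero;
zero-imputation happens only inside the scorer. Energy declared only in kcal
is converted at 4.184 kJ/kcal (the standard thermochemical factor); when
both units are declared and disagree by ≥ 0.5 kJ the row is flagged.

## Comparison layer

`crosstab_flows()` counts every (by-name, by-ingredients) pair among records
classified in both modes into a 4×4 flow table, tallying exclusions and
unclassified records separately; margin conservation is a tested invariant.
Derived statistics: `fold_change()` (column total / row total, to 1
decimal), `nova_share()` (the by-name denominator includes records later
excluded at the ingredient step, because they *were* classified by name),
`reclassified_share()` and `percent_increase()`.

Hypothesis tests are thin tidy wrappers over the standard implementations:
Pearson chi-square without continuity correction at any table size (for
consistency across shapes), Kruskal–Wallis with tie correction, and pairwise
Mann–Whitney U with Bonferroni adjustment (`min(1, p × n_pairs)`; exact p
for tie-free combined n ≤ 20, normal approximation with tie and continuity
correction otherwise). Group summaries are median (Q1, Q3) with type-7
(linear-interpolation) quantiles; the convention is not dictated by the
analysis being reproduced, so the common default was chosen and pinned.
The significance threshold defaults to α = 0.05.

## The synthetic generator

`generate_db()` draws a food table from a `synthetic_config()`: per
subcategory, a planted NOVA class, a product-name template pool that the
packaged lexicon recognizes as exactly that class, a class-consistent base
ingredient list, tier-1/tier-2 marker-insertion probabilities, and
log-normal nutrient distributions parameterized by their medians (nutrient
contents are positive and right-skewed, and median parameterization lets
published medians drop in directly). Ground truth (planted by-name class,
intended by-ingredient class, insertion and missingness events) is returned
as a separate table so pipeline code cannot accidentally read labels.

Reproducibility: one global seed drives a per-record counter-based
substream, so appending subcategories to a config leaves existing records
byte-identical.

Missingness: the config's `missing_negative_prob` is the *per-record*
probability that the negative-nutrient panel is incomplete (one of the four
masked at random). A per-nutrient-independent reading would make the
expected exclusion count 1 − (1 − p)⁴ of records, far above the documented
overall exclusion rate the preset encodes; the record-level reading makes
the excluded count Binomial(n, p), which is what the package's acceptance
properties check.

`helth_like_config()` emulates the structure of the real branded database
the analysis used: 13 categories, 4846 records planted to match the
published by-name distribution exactly, marker-insertion probabilities
solved per category from the published by-ingredient margins under
only-upward flows (so the expected reclassification flows match the
published table), nutrient medians seeded from the published per-stratum
medians (falling back to category-level and then global defaults where a
stratum is not printed), a 877/4851 record-level missing-negative rate and a
27/4851 missing-ingredient rate. Dispersion defaults to `sdlog = 0.5`, a
typical spread for within-category nutrient contents.

What the generator does *not* emulate: real product-name vocabulary beyond
the template pools (names are clean and always recognizable, so name-mode
recovery is 100% by construction — real names would include unclassifiable
ones), correlated missingness across nutrients, per-category missingness
differences (only a global rate is documented), multilingual text, and
quantitative ingredient declarations. Passing tests on synthetic data
therefore demonstrate the pipeline's internal correctness, not the
classifiers' recall on real supermarket names.

## Numerical choices and degenerate inputs

Scores are integers throughout — no rounding ambiguity. Thresholds are
strict inequalities; a value exactly on a threshold stays in the lower band.
Fold changes and percentages are reported to 1 decimal. A zero by-name
margin makes a fold change undefined (`NA` with a warning), and zero
chi-square margins are a precondition error. Empty groups in summaries are
reported with `n = 0` rather than dropped. Ties in Mann–Whitney U count
one half.

## Problem sizes in the test suite

The suite validates properties at the sizes the analysis design calls for:
1000 random nutrient panels for score range and monotonicity, the full
enumeration of 2×2 contingency tables with entries up to 20 against the
hand formula, exhaustive Mann–Whitney enumeration for group sizes up to 6,
and one full-size (n = 4846) synthetic database for ground-truth recovery
and the Binomial exclusion-count checks. Unit tests use smaller fixtures
built in code.

## Limitations

The packaged name lexicon covers exactly the published indicative-term
table; real product names will often be unclassifiable without extending
it. The E-number rule counts every additive as an ultra-processing marker
without a whitelist, which is deliberate but coarse (a few E-numbers are
plain culinary substances). The nutrient generator draws components
independently, so synthetic panels do not reproduce energy–macronutrient
consistency constraints. The comparison layer implements only the tests the
reproduced analysis used; it is not a general survey-statistics toolkit.
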