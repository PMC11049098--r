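# novascore

Dual-mode NOVA food-processing classification and Nutri-Score nutrient
profiling for branded food composition tables.

## The problem

Epidemiological work on ultra-processed foods (UPFs) hinges on assigning
packaged foods to the four NOVA groups — NOVA1 (unprocessed/minimally
processed), NOVA2 (culinary ingredients), NOVA3 (processed), NOVA4
(ultra-processed). Whether this is done from a food's *name only* (all that a
generic food composition database offers) or from its *name plus the
on-package ingredient list* (what a branded database offers) changes the
answer substantially: the ingredient list is where the markers of
ultra-processing — additives, industrial sweeteners, protein isolates,
emulsifiers, gums — actually appear.

`novascore` implements both modes as explicit rule systems over packaged,
user-replaceable lexicons, together with:

* an **FSAm-NPS / Nutri-Score engine**: four negative nutrients (energy kJ,
  total sugars g, saturated fat g, sodium mg) score 0–10 points each, three
  positive components (protein, fiber, FV%) score 0–5; the score is
  `negatives − positives ∈ [−15, 40]`, mapped to grades A–E with separate
  bands for solids, beverages, and waters;
* a **comparison layer**: 4×4 reclassification flow tables with fold changes
  and shares, chi-square, Kruskal–Wallis, pairwise Mann–Whitney U with
  Bonferroni correction, median (Q1, Q3) summaries, grade distributions;
* a **seeded synthetic generator** of branded-database-like food tables with
  known ground-truth classes, for end-to-end validation when the real
  (proprietary) data cannot be shipped.

Everything is tibble-in/tibble-out and pipe-friendly; results have
`tidy()`/`glance()` and `autoplot()` methods.

## Worked example

```r
library(novascore)

foods <- validate_food_table(tibble::tibble(
  record_id = c("f1", "f2", "f3", "f4"),
  product_name = c("plain yogurt", "frozen green beans",
                   "sweetened strawberry yogurt", "plain yogurt"),
  category = c("Dairy and Substitutes", "Vegetables and Vegetable Products",
               "Dairy and Substitutes", "Dairy and Substitutes"),
  subcategory = "misc", physical_state = "solid",
  ingredient_text = c("milk, yogurt cultures",
                      "green beans, water, salt",
                      "milk, sugar, strawberries, natural flavoring",
                      "milk, cultures, carrageenan"),
  energy_kj = c(270, 130, 390, 280), protein_g = c(4.5, 1.8, 3.1, 4.4),
  sfa_g = c(2.1, 0.1, 1.9, 2.2), sugars_g = c(4.6, 2.9, 12.4, 4.8),
  sodium_mg = c(55, 310, 60, 60), fiber_g = c(0, 2.9, 0.2, 0)))

nr <- classify_by_name(foods)
ir <- classify_by_ingredients(foods, nr)
dplyr::left_join(dplyr::select(nr, record_id, by_name = nova_group),
                 dplyr::select(ir, record_id, by_ingredients = nova_group),
                 by = "record_id")
#>   record_id by_name by_ingredients
#> 1 f1        NOVA1   NOVA1
#> 2 f2        NOVA1   NOVA3
#> 3 f3        NOVA4   NOVA4
#> 4 f4        NOVA1   NOVA4
```

By name, three of the four foods look minimally processed. The ingredient
list tells another story: the salt in the frozen beans makes them a
*processed* food (NOVA1 → NOVA3), and the carrageenan in the second "plain
yogurt" is an ultra-processing marker (NOVA1 → NOVA4). Scoring shows why
this matters — the reclassified yogurt is nutritionally indistinguishable
from the genuinely minimally processed one:

```r
score_table(foods) |> dplyr::select(record_id, fsam_nps, grade, status)
#>   record_id fsam_nps grade status
#> 1 f1               1 B     scored
#> 2 f2              -1 A     scored
#> 3 f3               3 C     scored
#> 4 f4               1 B     scored

flow <- crosstab_flows(nr, ir)
flow
#> NOVA reclassification flows (rows: by name; columns: by ingredients)
#>        by_ingredients
#> by_name NOVA1 NOVA2 NOVA3 NOVA4
#>   NOVA1     1     0     1     1
#>   NOVA2     0     0     0     0
#>   NOVA3     0     0     0     0
#>   NOVA4     0     0     0     1
fold_change(flow, 4)
#> [1] 2
```

`run_pipeline(foods)` chains all of the above and adds nutrient summaries,
tests, and grade distributions per NOVA group and per reclassification
stratum; `generate_db(helth_like_config(seed = 1))` produces a full-size
(n = 4846, 13-category) synthetic database with ground truth to exercise it.
A thin command-line wrapper with `simulate` / `classify` / `score` /
`compare` / `run` subcommands ships in `inst/scripts/novascore-cli.R`.

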