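#' Synthetic branded-food-database generation
#'
#' The generator produces food tables with known ground-truth NOVA classes
#' so the whole pipeline can be validated without access to a proprietary
#' branded database. Product names are drawn from class-consistent templates
#' that the packaged name lexicon recognizes; ingredient lists are built
#' from a class-consistent base with culinary (tier 1) and ultra-processing
#' (tier 2) markers inserted with configurable probabilities; nutrient
#' panels are drawn from per-stratum log-normal distributions parameterized
#' by their medians (nutrient contents are positive and right-skewed).
#'
#' @name synthetic_db
NULL

#' Build a synthetic-database configuration
#'
#' @param subcats Tibble with one row per synthetic subcategory:
#'   `subcategory`, `category`, `physical_state`, `n`, `planted_nova` (1-4),
#'   `tier1_prob`, `tier2_prob`, log-normal medians `energy_kcal`,
#'   `protein_g`, `sfa_g`, `sugars_g`, `sodium_mg`, optional `fiber_g` and
#'   `fv_percent` medians (`NA` = nutrient absent), and `sdlog` dispersion.
#' @param missing_negative_prob Per-record probability that the
#'   negative-nutrient panel is incomplete (one of the four masked at
#'   random), making the record unscorable.
#' @param missing_ingredient_prob Per-record probability that the ingredient
#'   list is unavailable.
#' @param seed Integer seed driving a per-record substream, so record-level
#'   reproducibility survives appending subcategories.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(subcats, missing_negative_prob = 0,
                             missing_ingredient_prob = 0, seed = 1L) {
  subcats <- as_tibble(subcats)
  needed <- c("subcategory", "category", "physical_state", "n",
              "planted_nova", "tier1_prob", "tier2_prob",
              "energy_kcal", "protein_g", "sfa_g", "sugars_g", "sodium_mg")
  missing <- setdiff(needed, names(subcats))
  bad <- character(0)
  if (length(missing) > 0) {
    bad <- c(bad, paste0("missing subcategory column(s): ",
                         paste(missing, collapse = ", ")))
  } else {
    if (any(subcats$n < 0)) bad <- c(bad, "n must be >= 0")
    if (!all(subcats$planted_nova %in% 1:4)) {
      bad <- c(bad, "planted_nova must be in 1-4")
    }
    probs <- c(subcats$tier1_prob, subcats$tier2_prob,
               missing_negative_prob, missing_ingredient_prob)
    if (any(probs < 0 | probs > 1)) bad <- c(bad, "probabilities must be in [0, 1]")
  }
  if (length(bad) > 0) {
    abort(paste0("Invalid synthetic config: ", paste(bad, collapse = "; ")))
  }
  if (!"fiber_g" %in% names(subcats)) subcats$fiber_g <- NA_real_
  if (!"fv_percent" %in% names(subcats)) subcats$fv_percent <- NA_real_
  if (!"sdlog" %in% names(subcats)) subcats$sdlog <- 0.5
  structure(
    list(subcats = subcats,
         missing_negative_prob = missing_negative_prob,
         missing_ingredient_prob = missing_ingredient_prob,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# class-consistent name and base-ingredient templates per category; every
# name is recognized by the packaged lexicon as its planted class, and every
# base ingredient list is marker-free for NOVA1 bases
synthetic_templates <- function() {
  t <- function(category, planted, names, ingredients) {
    tibble(category = category, planted_nova = planted,
           names = list(names), ingredients = list(ingredients))
  }
  bind_rows(
    t("Dairy and Substitutes", 1,
      c("fresh pasteurized milk", "plain yogurt", "greek yogurt"),
      c("pasteurized milk", "milk, yogurt cultures")),
    t("Dairy and Substitutes", 3,
      c("smoked cheese", "cured cheese"),
      c("milk, salt, rennet")),
    t("Dairy and Substitutes", 4,
      c("sweetened strawberry yogurt", "chocolate milk", "vanilla ice cream"),
      c("milk, sugar, strawberries")),
    t("Egg and Egg Products", 1, c("fresh eggs"), c("eggs")),
    t("Egg and Egg Products", 4, c("powdered eggs"), c("eggs, salt")),
    t("Meat and Meat Products", 1,
      c("fresh chicken fillet", "frozen beef steak"),
      c("chicken fillet", "beef")),
    t("Meat and Meat Products", 3,
      c("smoked bacon", "cured ham"), c("pork, salt")),
    t("Meat and Meat Products", 4,
      c("chicken nuggets", "pork sausages"),
      c("chicken, wheat flour, salt")),
    t("Seafood, Fish and Products", 3,
      c("canned tuna in brine", "smoked salmon"),
      c("tuna, water, salt")),
    t("Seafood, Fish and Products", 4,
      c("fish sticks", "breaded fish fingers"),
      c("fish, wheat flour, salt")),
    t("Fats and Oils", 2,
      c("olive oil", "butter", "sunflower oil"),
      c("olive oil", "butter")),
    t("Fats and Oils", 4,
      c("margarine", "vegetable spread"),
      c("vegetable oil, water")),
    t("Grains and Grain Products", 1,
      c("wheat flour", "dried pasta", "oat flakes", "rice"),
      c("wheat flour", "durum wheat semolina")),
    t("Grains and Grain Products", 3,
      c("fresh bread"), c("wheat flour, water, yeast, salt")),
    t("Grains and Grain Products", 4,
      c("breakfast cereal", "chocolate biscuits", "packaged bread"),
      c("wheat flour, sugar")),
    t("Nuts, Seeds, and Kernels", 1,
      c("raw almonds", "walnuts"), c("almonds", "walnuts")),
    t("Nuts, Seeds, and Kernels", 3,
      c("salted peanuts"), c("peanuts, salt")),
    t("Nuts, Seeds, and Kernels", 4,
      c("nut snack"), c("peanuts, sugar")),
    t("Vegetables and Vegetable Products", 1,
      c("frozen green beans", "fresh spinach"),
      c("green beans", "spinach")),
    t("Vegetables and Vegetable Products", 3,
      c("canned peas in brine", "pickled cucumbers"),
      c("peas, water, salt")),
    t("Vegetables and Vegetable Products", 4,
      c("instant vegetable soup"), c("vegetables, salt")),
    t("Fruit and Fruit Products", 1,
      c("dried fruit mix", "raisins"), c("raisins")),
    t("Fruit and Fruit Products", 3,
      c("peaches in syrup"), c("peaches, sugar, water")),
    t("Fruit and Fruit Products", 4,
      c("fruit snack"), c("dried fruit, sugar")),
    t("Sugars and Sugar Products", 1, c("dates"), c("dates")),
    t("Sugars and Sugar Products", 2,
      c("white sugar", "honey"), c("sugar", "honey")),
    t("Sugars and Sugar Products", 3,
      c("quince in syrup"), c("quince, sugar")),
    t("Sugars and Sugar Products", 4,
      c("milk chocolate", "strawberry jam"), c("sugar, cocoa")),
    t("Beverages", 1,
      c("orange juice", "mineral water", "coffee"),
      c("orange juice", "water")),
    t("Beverages", 4,
      c("carbonated soft drink", "cola drink", "sweetened juice"),
      c("water, sugar")),
    t("Ready Meals", 4,
      c("frozen pizza", "ready meal with pasta"),
      c("wheat flour, tomatoes, cheese")),
    t("Miscellaneous", 1,
      c("dried oregano", "black pepper"), c("oregano", "pepper")),
    t("Miscellaneous", 2, c("sea salt"), c("salt")),
    t("Miscellaneous", 3, c("tomato paste"), c("tomatoes, salt")),
    t("Miscellaneous", 4,
      c("tomato sauce", "instant soup mix", "seasoning mix"),
      c("tomatoes, salt"))
  )
}

tier1_insert_tokens <- c("salt", "sugar", "olive oil")
tier2_insert_tokens <- c("carrageenan", "aspartame", "glucose syrup",
                         "soy protein isolate", "natural flavoring",
                         "soy lecithin", "xanthan gum", "e322",
                         "sodium benzoate", "maltodextrin")

intended_ing_class <- function(planted, has_tier1, has_tier2) {
  if (planted == 4) return(4L)
  if (has_tier2) return(4L)
  if (has_tier1 && planted == 1) return(3L)
  as.integer(planted)
}

record_seed <- function(seed, subcat_idx, record_idx) {
  # counter-based substream keyed on (subcategory, record); stays < 2^31
  (as.double(seed) + 7919 * subcat_idx + 104729 * record_idx) %% 2147483629
}

#' Generate a synthetic branded food database
#'
#' @param config A [synthetic_config()].
#' @return A list with `foods` (validated `food_table` tibble) and `truth`
#'   (tibble with the planted by-name class and the intended by-ingredient
#'   class per record, plus the marker-insertion and missingness events).
#'   The truth table is deliberately separate from the food table so
#'   pipeline code cannot read labels by accident.
#' @export
generate_db <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must be a synthetic_config object.")
  }
  templates <- synthetic_templates()
  sub <- config$subcats

  all_foods <- vector("list", nrow(sub))
  all_truth <- vector("list", nrow(sub))
  for (i in seq_len(nrow(sub))) {
    s <- sub[i, ]
    if (s$n == 0) next
    tmpl <- templates[templates$category == s$category &
                        templates$planted_nova == s$planted_nova, ]
    if (nrow(tmpl) == 0) {
      abort(paste0("No name template for category '", s$category,
                   "' with planted NOVA", s$planted_nova, "."))
    }
    names_pool <- tmpl$names[[1]]
    ing_pool <- tmpl$ingredients[[1]]

    n <- s$n
    name <- character(n); ing <- character(n)
    has_tier1 <- logical(n); has_tier2 <- logical(n)
    ing_missing <- logical(n); masked <- rep(NA_character_, n)
    panel <- matrix(NA_real_, nrow = n, ncol = 7,
                    dimnames = list(NULL, c("energy_kj", "protein_g", "sfa_g",
                                            "sugars_g", "sodium_mg", "fiber_g",
                                            "fv_percent")))
    old <- .Random.seed_save()
    draw <- function(med, sd) {
      if (is.na(med)) return(NA_real_)
      round(rlnorm(1, meanlog = log(max(med, 0.01)), sdlog = sd), 2)
    }
    for (j in seq_len(n)) {
      set.seed(record_seed(config$seed, i, j))
      name[j] <- sample(names_pool, 1)
      base_ing <- sample(ing_pool, 1)
      has_tier2[j] <- runif(1) < s$tier2_prob
      has_tier1[j] <- !has_tier2[j] && runif(1) < s$tier1_prob
      ing_j <- base_ing
      if (has_tier1[j]) {
        ing_j <- paste(ing_j, sample(tier1_insert_tokens, 1), sep = ", ")
      }
      if (has_tier2[j]) {
        ing_j <- paste(ing_j, sample(tier2_insert_tokens, 1), sep = ", ")
      }
      ing[j] <- ing_j
      ing_missing[j] <- runif(1) < config$missing_ingredient_prob

      kcal <- draw(s$energy_kcal, s$sdlog)
      panel[j, ] <- c(round(kcal * KJ_PER_KCAL, 1),
                      draw(s$protein_g, s$sdlog),
                      draw(s$sfa_g, s$sdlog),
                      draw(s$sugars_g, s$sdlog),
                      draw(s$sodium_mg, s$sdlog),
                      draw(s$fiber_g, s$sdlog),
                      min(draw(s$fv_percent, s$sdlog), 100))
      if (runif(1) < config$missing_negative_prob) {
        masked[j] <- sample(negative_nutrients(), 1)
        panel[j, masked[j]] <- NA_real_
      }
    }
    .Random.seed_restore(old)

    all_foods[[i]] <- tibble(
      record_id = paste0("syn", i, "_", seq_len(n)),
      product_name = name,
      long_name = NA_character_,
      category = s$category,
      subcategory = s$subcategory,
      physical_state = s$physical_state,
      ingredient_text = if_else(ing_missing, NA_character_, ing),
      energy_kj = panel[, "energy_kj"],
      energy_kcal = NA_real_,
      protein_g = panel[, "protein_g"],
      sfa_g = panel[, "sfa_g"],
      sugars_g = panel[, "sugars_g"],
      sodium_mg = panel[, "sodium_mg"],
      fiber_g = panel[, "fiber_g"],
      fv_percent = panel[, "fv_percent"]
    )
    all_truth[[i]] <- tibble(
      record_id = paste0("syn", i, "_", seq_len(n)),
      subcategory = s$subcategory,
      truth_by_name = s$planted_nova,
      truth_by_ingredients = if_else(
        ing_missing, NA_integer_,
        purrr::map2_int(has_tier1, has_tier2,
                        ~ intended_ing_class(s$planted_nova, .x, .y))),
      has_tier1 = has_tier1,
      has_tier2 = has_tier2,
      ingredient_missing = ing_missing,
      negative_masked = masked
    )
  }
  foods <- suppressWarnings(validate_food_table(bind_rows(all_foods)))
  list(foods = foods, truth = bind_rows(all_truth))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# published category-level distribution of the two classification modes:
# by-name counts n1-n4 and by-ingredient counts m1-m4 per category
helth_category_counts <- function() {
  tibble::tribble(
    ~category, ~state, ~n1, ~n2, ~n3, ~n4, ~m1, ~m2, ~m3, ~m4,
    "Dairy and Substitutes", "solid", 365, 0, 264, 432, 146, 0, 187, 715,
    "Egg and Egg Products", "solid", 35, 0, 0, 1, 34, 0, 0, 2,
    "Meat and Meat Products", "solid", 8, 0, 129, 109, 1, 0, 2, 237,
    "Seafood, Fish and Products", "solid", 0, 0, 73, 9, 0, 0, 54, 27,
    "Fats and Oils", "solid", 0, 42, 0, 39, 0, 33, 0, 48,
    "Grains and Grain Products", "solid", 276, 0, 17, 849, 235, 0, 12, 894,
    "Nuts, Seeds, and Kernels", "solid", 62, 0, 58, 11, 29, 0, 34, 67,
    "Vegetables and Vegetable Products", "solid", 539, 0, 50, 27, 489, 0, 37, 88,
    "Fruit and Fruit Products", "solid", 20, 0, 25, 0, 1, 0, 5, 38,
    "Sugars and Sugar Products", "solid", 2, 35, 47, 321, 1, 35, 28, 341,
    "Beverages", "beverage", 119, 0, 0, 329, 48, 0, 1, 397,
    "Ready Meals", "solid", 0, 0, 0, 84, 0, 0, 0, 84,
    "Miscellaneous", "solid", 5, 1, 57, 406, 5, 1, 7, 460
  )
}

# per-category log-normal nutrient medians by planted class, seeded from the
# published per-stratum medians where available (kcal, g, g, g, mg)
helth_nutrient_medians <- function() {
  tibble::tribble(
    ~category, ~planted_nova, ~energy_kcal, ~protein_g, ~sfa_g, ~sugars_g, ~sodium_mg,
    "Dairy and Substitutes", 1, 50, 1.4, 0.9, 3.7, 52,
    "Dairy and Substitutes", 3, 279, 11, 18, 0.5, 700,
    "Dairy and Substitutes", 4, 96, 3.2, 1.3, 7.1, 48,
    "Egg and Egg Products", 1, 143, 12.6, 3.1, 0.4, 140,
    "Egg and Egg Products", 4, 160, 13, 3.5, 0.5, 400,
    "Meat and Meat Products", 1, 196, 19, 4.7, 1.1, 80,
    "Meat and Meat Products", 3, 215, 14.6, 4.3, 1.0, 952,
    "Meat and Meat Products", 4, 222, 16, 1.8, 1.1, 600,
    "Seafood, Fish and Products", 3, 187, 11.6, 2.1, 1.0, 628,
    "Seafood, Fish and Products", 4, 203, 12.3, 1.0, 0.9, 364,
    "Fats and Oils", 2, 737, 0.6, 52, 0.6, 20,
    "Fats and Oils", 4, 530, 0.2, 20, 0.5, 500,
    "Grains and Grain Products", 1, 358, 8.2, 0.7, 2.8, 5,
    "Grains and Grain Products", 3, 359.5, 12.6, 3.5, 3.7, 610,
    "Grains and Grain Products", 4, 399, 8, 4.9, 12.7, 320,
    "Nuts, Seeds, and Kernels", 1, 517.5, 14.9, 5.0, 5.3, 5,
    "Nuts, Seeds, and Kernels", 3, 574, 17.4, 6.0, 2.7, 528,
    "Nuts, Seeds, and Kernels", 4, 573, 18.4, 8.4, 7.4, 16,
    "Vegetables and Vegetable Products", 1, 20, 1.6, 0.1, 2.4, 28,
    "Vegetables and Vegetable Products", 3, 26, 1.5, 0.1, 3.5, 20,
    "Vegetables and Vegetable Products", 4, 136, 2.6, 0.6, 1.3, 52,
    "Fruit and Fruit Products", 1, 294, 2.4, 0.1, 47, 52,
    "Fruit and Fruit Products", 3, 68.5, 0.4, 0.05, 17.5, 10,
    "Fruit and Fruit Products", 4, 150, 1, 0.2, 30, 20,
    "Sugars and Sugar Products", 1, 290, 2, 0.3, 65, 2,
    "Sugars and Sugar Products", 2, 395, 0.1, 0.05, 99, 1,
    "Sugars and Sugar Products", 3, 420, 8, 0.1, 47, 24,
    "Sugars and Sugar Products", 4, 529, 6.2, 17, 48.1, 44,
    "Beverages", 1, 49, 0.3, 0.05, 11.5, 4,
    "Beverages", 4, 44, 0.1, 0.05, 7.9, 8,
    "Ready Meals", 4, 180, 7, 3, 3, 400,
    "Miscellaneous", 1, 350, 44.6, 1.0, 10, 3995,
    "Miscellaneous", 2, 1, 0.05, 0.05, 0.05, 38000,
    "Miscellaneous", 3, 77, 1.3, 0.1, 10, 720,
    "Miscellaneous", 4, 280, 3.3, 2.0, 3.3, 568
  )
}

#' Configuration emulating the structure of a large branded food database
#'
#' Builds a [synthetic_config()] with the 13 published food categories
#' (~4850 records), per-category planted-class counts matching the by-name
#' distribution, marker-insertion probabilities solved from the published
#' by-ingredient distribution (so the expected reclassification flows match
#' the published margins), nutrient medians seeded from the published
#' per-stratum medians, an 877/4851 record-level missing-negative-nutrient
#' rate and a 27/4851 missing-ingredient-list rate.
#'
#' @param seed Integer seed.
#' @return A `synthetic_config`.
#' @export
helth_like_config <- function(seed = 1L) {
  counts <- helth_category_counts()
  meds <- helth_nutrient_medians()

  rows <- purrr::pmap(counts, function(category, state, n1, n2, n3, n4,
                                       m1, m2, m3, m4) {
    # only-upward flows: stay, 1->3, 1->4, 2->4, 3->4
    t13 <- max(0, m3 - n3)
    stay3 <- m3 - t13
    t34 <- n3 - stay3
    t14 <- max(0, n1 - m1 - t13)
    t24 <- max(0, n2 - m2)
    spec_row <- function(planted, n, p1, p2) {
      if (n == 0) return(NULL)
      med <- meds[meds$category == category & meds$planted_nova == planted, ]
      if (nrow(med) == 0) {
        med <- tibble(energy_kcal = 250, protein_g = 5, sfa_g = 2,
                      sugars_g = 5, sodium_mg = 300)
      }
      plant_cat <- c("vegetable", "fruit", "nuts", "pulse")
      plant <- any(stringr::str_detect(tolower(category), plant_cat))
      tibble(
        subcategory = paste0(category, " / planted NOVA", planted),
        category = category, physical_state = state, n = n,
        planted_nova = planted, tier1_prob = p1, tier2_prob = p2,
        energy_kcal = med$energy_kcal, protein_g = med$protein_g,
        sfa_g = med$sfa_g, sugars_g = med$sugars_g,
        sodium_mg = med$sodium_mg,
        fiber_g = if (plant) 3 else if (planted == 2) NA_real_ else 1,
        fv_percent = if (plant) 80 else NA_real_,
        sdlog = 0.5
      )
    }
    bind_rows(
      spec_row(1, n1,
               p1 = if (n1 - t14 > 0) t13 / (n1 - t14) else 0,
               p2 = if (n1 > 0) t14 / n1 else 0),
      spec_row(2, n2, p1 = 0, p2 = if (n2 > 0) t24 / n2 else 0),
      spec_row(3, n3, p1 = 0.5, p2 = if (n3 > 0) t34 / n3 else 0),
      spec_row(4, n4, p1 = 0.3, p2 = 1)
    )
  })
  synthetic_config(
    bind_rows(rows),
    missing_negative_prob = 877 / 4851,
    missing_ingredient_prob = 27 / 4851,
    seed = seed
  )
}
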