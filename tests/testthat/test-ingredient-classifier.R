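test_that("ingredient tokenization splits lists and extracts parentheticals", {
  expect_equal(tokenize_ingredients("milk, yogurt cultures"),
               c("milk", "yogurt cultures"))
  expect_setequal(
    tokenize_ingredients("wheat flour (wheat, malted barley), salt"),
    c("wheat flour", "wheat", "malted barley", "salt"))
  expect_equal(tokenize_ingredients(""), character(0))
  expect_equal(tokenize_ingredients(NA_character_), character(0))
  # percentage annotations are stripped, case folded
  expect_setequal(tokenize_ingredients("Tomatoes 80%; Salt"),
                  c("tomatoes", "salt"))
})

test_that("marker detection reports tier and class per hit", {
  h <- detect_markers(c("milk", "carrageenan"))
  expect_equal(h$tier, "tier2")
  expect_equal(h$class, "thickeners_gums")
  expect_equal(h$token, "carrageenan")

  h <- detect_markers(c("green beans", "water", "salt"))
  expect_equal(h$tier, "tier1")
  expect_equal(h$token, "salt")

  h <- detect_markers(c("cocoa", "e322"))
  expect_true(any(h$class == "e_numbers" & h$token == "e322"))
})

test_that("E-number detection needs 3-4 digits and word boundaries", {
  expect_equal(nrow(detect_markers(c("e12", "e32234", "sec322"))), 0)
  expect_equal(detect_markers("e1520")$class, "e_numbers")
  expect_equal(detect_markers("emulsifier e471")$class,
               c("emulsifiers", "e_numbers"))
})

test_that("water, yeast and cultures are neutral tokens", {
  expect_equal(nrow(detect_markers(c("water", "yeast", "yogurt cultures"))), 0)
})

test_that("fortification iron is exempt in the milled-grain category only", {
  h_grain <- detect_markers(c("wheat flour", "iron"),
                            category = "Grains and Grain Products")
  expect_equal(nrow(h_grain), 0)
  h_other <- detect_markers(c("wheat flour", "iron"), category = "Beverages")
  expect_equal(h_other$class, "industrial_nutrient_forms")
})

test_that("ingredient-based classes follow the marker cascade", {
  foods <- make_food_table(
    c("plain yogurt", "frozen green beans", "plain yogurt", "salted butter",
      "smoked bacon", "packaged bread", "fresh pasteurized milk"),
    ingredient_text = c(
      "milk, yogurt cultures",
      "green beans, water, salt",
      "milk, cultures, carrageenan",
      "butter, salt",
      "pork, salt",
      "wheat flour, water, yeast, salt",
      NA
    ))
  nr <- classify_by_name(foods)
  ir <- classify_by_ingredients(foods, nr)
  expect_equal(as.character(ir$nova_group),
               c("NOVA1", "NOVA3", "NOVA4", "NOVA2", "NOVA3", "NOVA4", NA))
  expect_equal(ir$status[7], "excluded_no_ingredients")
  # tier-1 hit on a NOVA2 culinary base does not promote
  expect_equal(as.character(ir$nova_group[4]), "NOVA2")
  # name-based NOVA4 is sticky even with innocuous ingredients
  expect_equal(as.character(ir$nova_group[6]), "NOVA4")
})

test_that("classification requires a name result covering all records", {
  foods <- make_food_table("plain yogurt", ingredient_text = "milk")
  expect_error(classify_by_ingredients(foods, NULL), "name_results")
  nr <- classify_by_name(make_food_table("something else"))
  nr$record_id <- "other"
  expect_error(classify_by_ingredients(foods, nr), "cover every record")
})

test_that("appending a tier-2 marker always yields NOVA4 and water never changes the class", {
  base <- c("milk, cultures", "green beans, salt", "pork, salt",
            "wheat flour", "butter", "sugar, cocoa")
  names <- c("plain yogurt", "frozen green beans", "smoked bacon",
             "dried pasta", "butter", "milk chocolate")
  markers <- c("carrageenan", "aspartame", "natural flavoring", "e322",
               "maltodextrin", "soy lecithin")
  set.seed(101)
  for (i in seq_along(base)) {
    mk <- sample(markers, 1)
    foods <- make_food_table(
      rep(names[i], 3),
      ingredient_text = c(base[i],
                          paste(base[i], mk, sep = ", "),
                          paste(base[i], "water", sep = ", ")))
    nr <- classify_by_name(foods)
    ir <- classify_by_ingredients(foods, nr)
    expect_equal(as.character(ir$nova_group[2]), "NOVA4",
                 info = paste(names[i], "+", mk))
    expect_equal(ir$nova_group[3], ir$nova_group[1],
                 info = paste(names[i], "+ water"))
  }
})

test_that("the ingredient mode never demotes below the name-based class", {
  cfg <- synthetic_config(helth_like_config(seed = 11)$subcats,
                          missing_negative_prob = 0,
                          missing_ingredient_prob = 0, seed = 11)
  cfg$subcats$n <- pmin(cfg$subcats$n, 15L)
  db <- generate_db(cfg)
  nr <- classify_by_name(db$foods)
  ir <- classify_by_ingredients(db$foods, nr)
  bn <- novascore:::nova_int(nr$nova_group)
  bi <- novascore:::nova_int(ir$nova_group)
  both <- !is.na(bn) & !is.na(bi)
  expect_true(all(bi[both] >= bn[both]))
  # the only non-NOVA4 promotion is NOVA1 -> NOVA3
  promoted <- both & bi > bn & bi != 4
  expect_true(all(bn[promoted] == 1 & bi[promoted] == 3))
})
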