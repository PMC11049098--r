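#' FSAm-NPS point thresholds
#'
#' Loads the packaged threshold table (component, scale, threshold, points).
#' A component's points are the highest `points` value whose `threshold` is
#' strictly exceeded ("greater than" bands), 0 otherwise. The beverage scale
#' exists for energy, sugars and the fruit/vegetable/pulse/nut/oil share
#' (FV%); other components use the food scale everywhere.
#'
#' @param path Optional path to a custom threshold CSV.
#' @return A tibble of thresholds.
#' @export
nutriscore_thresholds <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nutriscore_thresholds.csv",
                        package = "novascore", mustWork = TRUE)
  }
  readr::read_csv(path, col_types = readr::cols(
    component = "c", scale = "c", threshold = "d", points = "i"),
    progress = FALSE)
}

points_for <- function(value, component, scale, thresholds) {
  rows <- thresholds[thresholds$component == component &
                       thresholds$scale == scale, ]
  if (nrow(rows) == 0) {  # no beverage-specific scale: fall back to food
    rows <- thresholds[thresholds$component == component &
                         thresholds$scale == "food", ]
  }
  vapply(value, function(v) {
    if (is.na(v)) return(NA_integer_)
    exceeded <- rows$points[v > rows$threshold]
    if (length(exceeded) == 0) 0L else max(exceeded)
  }, integer(1))
}

#' Points for the "negative" nutrients
#'
#' Energy (kJ), total sugars (g), saturated fat (g) and sodium (mg) each
#' score 0--10 points for increasing content. Under the `"paper"` preset the
#' food scale applies to every product; under `"fsam2017_full"` beverages use
#' the beverage-specific energy and sugar scales.
#'
#' @param energy_kj,sugars_g,sfa_g,sodium_mg Contents per 100 g/mL. All four
#'   must be present; a missing value yields `NA` points (the caller excludes
#'   such records).
#' @param preset `"paper"` or `"fsam2017_full"`.
#' @param physical_state `"solid"`, `"beverage"` or `"water"` (vectorized).
#' @param thresholds Threshold table, see [nutriscore_thresholds()].
#' @return Tibble with `energy_pts`, `sugars_pts`, `sfa_pts`, `sodium_pts`.
#' @export
negative_points <- function(energy_kj, sugars_g, sfa_g, sodium_mg,
                            preset = c("paper", "fsam2017_full"),
                            physical_state = "solid",
                            thresholds = nutriscore_thresholds()) {
  preset <- arg_match(preset)
  n <- max(length(energy_kj), length(sugars_g), length(sfa_g),
           length(sodium_mg))
  energy_kj <- rep_len(energy_kj, n); sugars_g <- rep_len(sugars_g, n)
  sfa_g <- rep_len(sfa_g, n); sodium_mg <- rep_len(sodium_mg, n)
  state <- rep_len(physical_state, n)
  scale <- if (preset == "paper") rep("food", n) else
    if_else(state %in% c("beverage", "water"), "beverage", "food")
  pts <- function(value, comp) {
    out <- integer(n)
    for (s in unique(scale)) {
      idx <- scale == s
      out[idx] <- points_for(value[idx], comp, s, thresholds)
    }
    out
  }
  tibble(
    energy_pts = pts(energy_kj, "energy"),
    sugars_pts = pts(sugars_g, "sugars"),
    sfa_pts = pts(sfa_g, "sfa"),
    sodium_pts = pts(sodium_mg, "sodium")
  )
}

#' Points for the "positive" nutrients
#'
#' Protein (g), fiber (g) and FV% each score 0--5 points for increasing
#' content (FV% scores 0--10 on the full-model beverage scale). Missing
#' values are treated as zero by the caller's imputation policy; here they
#' yield 0 points.
#'
#' @inheritParams negative_points
#' @param protein_g,fiber_g,fv_percent Contents per 100 g/mL.
#' @return Tibble with `protein_pts`, `fiber_pts`, `fv_pts`.
#' @export
positive_points <- function(protein_g, fiber_g, fv_percent,
                            preset = c("paper", "fsam2017_full"),
                            physical_state = "solid",
                            thresholds = nutriscore_thresholds()) {
  preset <- arg_match(preset)
  n <- max(length(protein_g), length(fiber_g), length(fv_percent))
  protein_g <- rep_len(protein_g, n); fiber_g <- rep_len(fiber_g, n)
  fv_percent <- rep_len(fv_percent, n)
  state <- rep_len(physical_state, n)
  scale <- if (preset == "paper") rep("food", n) else
    if_else(state %in% c("beverage", "water"), "beverage", "food")
  zero_na <- function(x) if_else(is.na(x), 0, as.numeric(x))
  pts <- function(value, comp) {
    out <- integer(n)
    for (s in unique(scale)) {
      idx <- scale == s
      out[idx] <- points_for(value[idx], comp, s, thresholds)
    }
    out
  }
  tibble(
    protein_pts = pts(zero_na(protein_g), "protein"),
    fiber_pts = pts(zero_na(fiber_g), "fiber"),
    fv_pts = pts(zero_na(fv_percent), "fv")
  )
}

#' Combine component points into the FSAm-NPS score
#'
#' The score is the negative-nutrient total minus the positive-nutrient
#' total. Under `"fsam2017_full"` the published protein cap applies: protein
#' points are not subtracted when the negative total reaches 11 unless the
#' food has maximal FV points or is a cheese.
#'
#' @param points A tibble with the seven `*_pts` columns (as produced by
#'   [negative_points()] and [positive_points()] combined).
#' @param preset `"paper"` or `"fsam2017_full"`.
#' @param is_cheese Logical (vectorized); cheeses keep their protein points
#'   under the full model.
#' @param fv_max Maximal FV points on the applicable scale (5 for foods,
#'   10 for beverages under the full model).
#' @return Integer score, in [-15, 40] under the `"paper"` preset.
#' @export
fsam_nps <- function(points, preset = c("paper", "fsam2017_full"),
                     is_cheese = FALSE, fv_max = 5L) {
  preset <- arg_match(preset)
  neg <- points$energy_pts + points$sugars_pts + points$sfa_pts +
    points$sodium_pts
  protein <- points$protein_pts
  if (preset == "fsam2017_full") {
    capped <- neg >= 11 & points$fv_pts < rep_len(fv_max, length(neg)) &
      !rep_len(is_cheese, length(neg))
    protein <- if_else(capped, 0L, protein)
  }
  as.integer(neg - (protein + points$fiber_pts + points$fv_pts))
}

#' Assign the five-level Nutri-Score grade
#'
#' Solid foods: A for scores up to -1, B for 0--2, C for 3--10, D for 11--18,
#' E for 19--40. Beverages are graded more strictly and never receive A:
#' B up to 1, C 2--5, D 6--9, E 10--40. Waters are always A.
#'
#' @param score Integer FSAm-NPS score in [-15, 40].
#' @param physical_state `"solid"`, `"beverage"` or `"water"` (vectorized).
#' @return Factor grade A-E.
#' @export
assign_grade <- function(score, physical_state) {
  n <- length(score)
  state <- rep_len(physical_state, n)
  ok <- is.na(score) | (score >= -15 & score <= 40)
  if (!all(ok)) abort("FSAm-NPS score out of range [-15, 40].")
  if (!all(state %in% c("solid", "beverage", "water"))) {
    abort("physical_state must be solid, beverage or water.")
  }
  grade <- case_when(
    is.na(score) ~ NA_character_,
    state == "water" ~ "A",
    state == "beverage" & score <= 1 ~ "B",
    state == "beverage" & score <= 5 ~ "C",
    state == "beverage" & score <= 9 ~ "D",
    state == "beverage" ~ "E",
    score <= -1 ~ "A",
    score <= 2 ~ "B",
    score <= 10 ~ "C",
    score <= 18 ~ "D",
    .default = "E"
  )
  factor(grade, levels = c("A", "B", "C", "D", "E"))
}

#' Score and grade a food table
#'
#' Applies the exclusion and imputation policy: records missing any negative
#' nutrient (energy, sugars, saturated fat, sodium) cannot be scored and are
#' flagged `excluded_missing_negative`; missing positive nutrients are
#' imputed with zero and listed per record in `imputed_positives`.
#'
#' @param foods A validated food table.
#' @param preset `"paper"` (simple subtraction, food scales throughout; the
#'   default) or `"fsam2017_full"` (beverage scales and protein cap).
#' @param thresholds Threshold table, see [nutriscore_thresholds()].
#' @return A tibble with one row per record: the seven component point
#'   columns, `fsam_nps`, `grade`, `status` and `imputed_positives`.
#' @export
score_table <- function(foods, preset = c("paper", "fsam2017_full"),
                        thresholds = nutriscore_thresholds()) {
  preset <- arg_match(preset)
  foods <- as_tibble(foods)
  state <- foods$physical_state

  neg <- negative_points(foods$energy_kj, foods$sugars_g, foods$sfa_g,
                         foods$sodium_mg, preset = preset,
                         physical_state = state, thresholds = thresholds)
  pos <- positive_points(foods$protein_g, foods$fiber_g, foods$fv_percent,
                         preset = preset, physical_state = state,
                         thresholds = thresholds)
  missing_neg <- is.na(foods$energy_kj) | is.na(foods$sugars_g) |
    is.na(foods$sfa_g) | is.na(foods$sodium_mg)

  imputed <- purrr::pmap(
    list(foods$protein_g, foods$fiber_g, foods$fv_percent),
    function(p, f, v) positive_nutrients()[c(is.na(p), is.na(f), is.na(v))]
  )
  subcat <- foods$subcategory %||% rep(NA_character_, nrow(foods))
  is_cheese <- stringr::str_detect(tolower(dplyr::coalesce(subcat, "")),
                                   "cheese")
  fv_max <- if (preset == "paper") 5L else
    if_else(state %in% c("beverage", "water"), 10L, 5L)
  score <- fsam_nps(bind_cols(neg, pos), preset = preset,
                    is_cheese = is_cheese, fv_max = fv_max)
  score[missing_neg] <- NA_integer_

  tibble(
    record_id = foods$record_id,
    physical_state = state,
    !!!neg, !!!pos,
    fsam_nps = score,
    grade = assign_grade(score, state),
    status = if_else(missing_neg, "excluded_missing_negative", "scored"),
    imputed_positives = imputed
  )
}
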