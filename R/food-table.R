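#' Column schema for branded food composition tables
#'
#' A food table has one row per packaged product. Mandatory columns identify
#' and categorize the product; the remaining columns carry the on-package
#' ingredient list and the nutrient declaration per 100 g (solids) or
#' 100 mL (beverages).
#'
#' @return Character vector of the canonical column names, in order.
#' @export
food_table_columns <- function() {
  c("record_id", "product_name", "long_name", "category", "subcategory",
    "physical_state", "ingredient_text",
    "energy_kj", "energy_kcal", "protein_g", "sfa_g", "sugars_g",
    "sodium_mg", "fiber_g", "fv_percent")
}

mandatory_columns <- function() {
  c("record_id", "product_name", "category", "subcategory", "physical_state")
}

nutrient_columns <- function() {
  c("energy_kj", "energy_kcal", "protein_g", "sfa_g", "sugars_g",
    "sodium_mg", "fiber_g", "fv_percent")
}

#' Nutrients treated as "negative" by the FSAm-NPS model
#'
#' Energy, total sugars, saturated fat and sodium. A record missing any of
#' these cannot be scored and is excluded by [score_table()].
#'
#' @return Character vector of column names.
#' @export
negative_nutrients <- function() c("energy_kj", "sugars_g", "sfa_g", "sodium_mg")

#' Nutrients treated as "positive" by the FSAm-NPS model
#' @return Character vector of column names.
#' @export
positive_nutrients <- function() c("protein_g", "fiber_g", "fv_percent")

KJ_PER_KCAL <- 4.184

#' Convert declared salt to sodium
#'
#' Nutrient declarations sometimes carry salt rather than sodium; the
#' conventional conversion is 1 g salt = 400 mg sodium.
#'
#' @param salt_g Salt in grams per 100 g/mL; must be non-negative.
#' @return Sodium in mg per 100 g/mL.
#' @export
#' @examples
#' salt_to_sodium(1)   # 400
#' salt_to_sodium(2.5) # 1000
salt_to_sodium <- function(salt_g) {
  if (any(!is.na(salt_g) & salt_g < 0)) {
    abort("`salt_g` must be non-negative.")
  }
  salt_g * 400
}

#' Validate a food table and harmonize its energy declaration
#'
#' Checks the schema (mandatory columns, unique `record_id`), row-level
#' validity (non-negative nutrients, `fv_percent` within 0--100, known
#' `physical_state`), fills `energy_kj` from `energy_kcal` (x 4.184) when only
#' kcal is declared, and flags rows where both energies are declared but
#' disagree by 0.5 kJ or more. Missing numeric cells stay missing (`NA`);
#' zero-imputation is a scoring-time policy, not a loading-time one.
#'
#' Rows that fail validation are dropped from the returned table and reported
#' in the `problems` attribute (a tibble with `row`, `record_id`, `reason`),
#' with a warning.
#'
#' @param x A data frame with the columns of [food_table_columns()] (missing
#'   optional columns are added as `NA`).
#' @return A validated tibble of class `food_table`, with attribute
#'   `problems`.
#' @export
validate_food_table <- function(x) {
  x <- as_tibble(x)

  missing_cols <- setdiff(mandatory_columns(), names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in setdiff(food_table_columns(), names(x))) {
    x[[col]] <- if (col %in% nutrient_columns()) NA_real_ else NA_character_
  }
  x <- x[food_table_columns()]
  x <- mutate(x, across(all_of(nutrient_columns()), as.numeric),
              across(!all_of(nutrient_columns()), as.character))

  dup <- x$record_id[duplicated(x$record_id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate record_id(s): ",
                 paste(unique(dup), collapse = ", ")))
  }

  problems <- tibble(row = integer(), record_id = character(),
                     reason = character())
  bad <- function(rows, reason) {
    tibble(row = which(rows), record_id = x$record_id[rows], reason = reason)
  }

  neg_cols <- setdiff(nutrient_columns(), "fv_percent")
  neg_bad <- rep(FALSE, nrow(x))
  for (col in neg_cols) {
    hit <- !is.na(x[[col]]) & (x[[col]] < 0 | !is.finite(x[[col]]))
    if (any(hit)) {
      problems <- bind_rows(problems, bad(hit, paste0(col, " negative or non-finite")))
    }
    neg_bad <- neg_bad | hit
  }
  fv_bad <- !is.na(x$fv_percent) &
    (x$fv_percent < 0 | x$fv_percent > 100 | !is.finite(x$fv_percent))
  if (any(fv_bad)) {
    problems <- bind_rows(problems, bad(fv_bad, "fv_percent outside [0, 100]"))
  }
  state_bad <- !(x$physical_state %in% c("solid", "beverage", "water"))
  if (any(state_bad)) {
    problems <- bind_rows(problems, bad(state_bad, "unknown physical_state"))
  }
  name_bad <- is.na(x$product_name) | trimws(x$product_name) == ""
  if (any(name_bad)) {
    problems <- bind_rows(problems, bad(name_bad, "empty product_name"))
  }

  # energy harmonization: kcal-only rows get kJ; disagreement >= 0.5 kJ flagged
  only_kcal <- is.na(x$energy_kj) & !is.na(x$energy_kcal)
  x$energy_kj[only_kcal] <- x$energy_kcal[only_kcal] * KJ_PER_KCAL
  both <- !is.na(x$energy_kj) & !is.na(x$energy_kcal)
  inconsistent <- both & abs(x$energy_kj - KJ_PER_KCAL * x$energy_kcal) >= 0.5
  if (any(inconsistent)) {
    problems <- bind_rows(problems,
                          bad(inconsistent, "energy_kj and energy_kcal inconsistent"))
  }

  drop <- name_bad | state_bad | fv_bad | neg_bad
  if (any(drop)) {
    warn(paste0(sum(drop), " row(s) failed validation and were dropped; ",
                "see attr(, 'problems')."))
  }
  out <- x[!drop, ]
  attr(out, "problems") <- problems
  class(out) <- c("food_table", class(out))
  out
}

#' Read a branded food composition table
#'
#' @param path Path to a CSV or JSON file using the canonical column names of
#'   [food_table_columns()].
#' @param format `"csv"` or `"json"`; guessed from the file extension by
#'   default.
#' @return A validated `food_table` tibble (see [validate_food_table()]).
#' @export
read_food_table <- function(path, format = c("auto", "csv", "json")) {
  format <- arg_match(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  raw <- switch(format,
    csv = readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE),
    json = as_tibble(jsonlite::fromJSON(path))
  )
  validate_food_table(raw)
}

#' Write a food table to CSV or JSON
#'
#' @param x A food table (validated or not).
#' @param path Output path.
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_food_table <- function(x, path, format = c("auto", "csv", "json")) {
  format <- arg_match(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  x <- as_tibble(x)[intersect(food_table_columns(), names(as_tibble(x)))]
  switch(format,
    csv = readr::write_csv(x, path, na = ""),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                na = "null")
  )
  invisible(path)
}
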