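#' Lexicons for rule-based NOVA classification
#'
#' Two packaged lexicons drive the classifiers. The *name lexicon* maps word
#' patterns found in product names to NOVA groups (one row per rule, with
#' `required_terms` that must all match, `any_terms` of which at least one
#' must match, and `forbidden_terms` none of which may match). The *marker
#' lexicon* lists ingredient-list markers in two tiers: tier 1 are culinary
#' ingredients (salt, sugar, honey, oils, butter, starch, vinegar) whose
#' addition to a minimally processed base makes a food *processed* (NOVA3);
#' tier 2 are ultra-processing markers (non-caloric sweeteners, industrial
#' caloric sweeteners, protein isolates, flavors, emulsifiers, gums and
#' thickeners, preservatives/antioxidants, industrial nutrient forms, and
#' E-numbers) that make a food *ultra-processed* (NOVA4).
#'
#' Both ship as plain CSV under `inst/extdata` so they can be inspected,
#' versioned, and replaced by user-supplied files.
#'
#' @name lexicons
NULL

split_terms <- function(x) {
  x[is.na(x)] <- ""
  strsplit(x, "|", fixed = TRUE) %>%
    purrr::map(~ trimws(.x[.x != ""]))
}

#' Read a name-classification lexicon
#'
#' @param path CSV with columns `rule_id`, `nova_group`, `required_terms`,
#'   `any_terms`, `forbidden_terms`, `category_scope` (the three term columns
#'   and the scope are `|`-separated lists; empty means "no constraint").
#' @return A validated lexicon tibble with list-columns of patterns.
#' @export
read_name_lexicon <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("rule_id", "nova_group", "required_terms", "any_terms",
              "forbidden_terms")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Lexicon is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"category_scope" %in% names(raw)) raw$category_scope <- NA_character_
  lex <- tibble(
    rule_id = raw$rule_id,
    nova_group = as.integer(raw$nova_group),
    required = split_terms(raw$required_terms),
    any = split_terms(raw$any_terms),
    forbidden = split_terms(raw$forbidden_terms),
    category_scope = split_terms(raw$category_scope)
  )
  validate_name_lexicon(lex)
}

validate_name_lexicon <- function(lex) {
  if (any(duplicated(lex$rule_id))) abort("Duplicate rule_id in lexicon.")
  if (!all(lex$nova_group %in% 1:4)) abort("nova_group must be 1-4.")
  empty <- purrr::map2_lgl(lex$required, lex$any,
                           ~ length(.x) == 0 && length(.y) == 0)
  if (any(empty)) {
    abort(paste0("Rule(s) with neither required nor any terms: ",
                 paste(lex$rule_id[empty], collapse = ", ")))
  }
  all_pat <- unlist(c(lex$required, lex$any, lex$forbidden))
  if (any(all_pat != tolower(all_pat))) {
    abort("Lexicon patterns must be lowercase.")
  }
  lex
}

#' @rdname read_name_lexicon
#' @export
default_name_lexicon <- function() {
  read_name_lexicon(system.file("extdata", "name_lexicon.csv",
                                package = "novascore", mustWork = TRUE))
}

#' Read an ingredient marker lexicon
#'
#' @param path CSV with columns `tier` (`tier1`/`tier2`), `class` (marker
#'   class, e.g. `emulsifiers`), `pattern` (lowercase word pattern) and
#'   optional `exempt_category` (food category in which the marker does not
#'   count, e.g. iron fortification of milled grains).
#' @return A validated marker-lexicon tibble.
#' @export
read_marker_lexicon <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("tier", "class", "pattern")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Marker lexicon is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"exempt_category" %in% names(raw)) raw$exempt_category <- NA_character_
  lex <- tibble(tier = raw$tier, class = raw$class,
                pattern = trimws(raw$pattern),
                exempt_category = raw$exempt_category)
  if (!all(lex$tier %in% c("tier1", "tier2"))) {
    abort("tier must be 'tier1' or 'tier2'.")
  }
  if (any(lex$pattern != tolower(lex$pattern))) {
    abort("Marker patterns must be lowercase.")
  }
  overlap <- intersect(lex$pattern[lex$tier == "tier1"],
                       lex$pattern[lex$tier == "tier2"])
  if (length(overlap) > 0) {
    abort(paste0("Pattern(s) in both tiers: ", paste(overlap, collapse = ", ")))
  }
  lex
}

#' @rdname read_marker_lexicon
#' @export
default_marker_lexicon <- function() {
  read_marker_lexicon(system.file("extdata", "marker_lexicon.csv",
                                  package = "novascore", mustWork = TRUE))
}

# whole-word phrase match of lowercase `pattern` inside normalized `text`
phrase_regex <- function(pattern) {
  escaped <- stringr::str_replace_all(
    pattern, "([.\\\\+*?\\[\\]^$(){}=!<>|:#])", "\\\\\\1")
  paste0("(?<![a-z0-9])", stringr::str_replace_all(escaped, " ", "\\\\s+"),
         "(?![a-z0-9])")
}

phrase_in <- function(text, pattern) {
  stringr::str_detect(text, stringr::regex(phrase_regex(pattern)))
}
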