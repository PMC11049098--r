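#' Tokenize an on-package ingredient list
#'
#' Splits free-text ingredient declarations on commas and semicolons,
#' recursively extracts parenthetical sub-ingredients as additional tokens,
#' strips percentage annotations, lowercases and folds spelling variants.
#'
#' @param ingredient_text Free text as printed on pack; `NA` or empty gives
#'   an empty token list.
#' @return Character vector of normalized ingredient tokens.
#' @export
#' @examples
#' tokenize_ingredients("Wheat flour (wheat, malted barley), salt")
#' # "wheat flour" "wheat" "malted barley" "salt"
tokenize_ingredients <- function(ingredient_text) {
  if (is.null(ingredient_text) || length(ingredient_text) == 0 ||
      is.na(ingredient_text) || trimws(ingredient_text) == "") {
    return(character(0))
  }
  text <- tolower(ingredient_text)
  # pull nested parentheticals out, innermost last; keep their contents as
  # additional comma-separated material
  extracted <- character(0)
  repeat {
    inner <- stringr::str_match_all(text, "\\(([^()]*)\\)")[[1]]
    if (nrow(inner) == 0) break
    extracted <- c(extracted, inner[, 2])
    text <- stringr::str_replace_all(text, "\\([^()]*\\)", " ")
  }
  pieces <- unlist(strsplit(c(text, extracted), "[,;]"))
  pieces <- stringr::str_replace_all(pieces, "[0-9]+(\\.[0-9]+)?\\s*%", " ")
  pieces <- stringr::str_replace_all(pieces, "[^a-z0-9]+", " ")
  pieces <- stringr::str_squish(pieces)
  pieces <- pieces[pieces != ""]
  vapply(pieces, fold_spelling, character(1), USE.NAMES = FALSE)
}

e_number_regex <- "(?<![a-z0-9])e[0-9]{3,4}[a-z]?(?![a-z0-9])"

# tokens never counted as markers: present in traditional processing
neutral_tokens <- c("water", "yeast", "cultures", "yogurt cultures",
                    "lactic cultures", "milk cultures", "rennet")

#' Detect processing markers in an ingredient token list
#'
#' Screens tokens against the two-tier marker lexicon. Tier 1 hits are
#' culinary ingredients (salt, sugar, oils, ...); tier 2 hits are
#' ultra-processing markers reported by class. Any token of the form
#' E + 3--4 digits (e.g. `e322`) is reported as a tier 2 `e_numbers` hit
#' without needing a lexicon entry.
#'
#' @param tokens Normalized tokens from [tokenize_ingredients()].
#' @param lexicon A marker lexicon (default: packaged).
#' @param category Optional food category, used for category-scoped
#'   exemptions (e.g. iron/folic acid fortification of milled grains).
#' @return A tibble with one row per hit: `tier`, `class`, `pattern`,
#'   `token`.
#' @export
detect_markers <- function(tokens, lexicon = default_marker_lexicon(),
                           category = NULL) {
  hits <- marker_hits_for_tokens(unique(tokens), lexicon)
  if (!is.null(category)) {
    drop <- !is.na(hits$exempt_category) & hits$exempt_category == category
    hits <- hits[!drop, ]
  }
  select(hits, "tier", "class", "pattern", "token")
}

# match every lexicon pattern (plus the E-number rule) against a token
# vocabulary; neutral tokens never hit
marker_hits_for_tokens <- function(tokens, lexicon) {
  empty <- tibble(tier = character(), class = character(),
                  pattern = character(), token = character(),
                  exempt_category = character())
  tokens <- setdiff(tokens, neutral_tokens)
  if (length(tokens) == 0) return(empty)

  per_pattern <- purrr::pmap(lexicon, function(tier, class, pattern,
                                               exempt_category, ...) {
    hit <- stringr::str_detect(tokens, stringr::regex(phrase_regex(pattern)))
    if (!any(hit)) return(NULL)
    tibble(tier = tier, class = class, pattern = pattern,
           token = tokens[hit], exempt_category = exempt_category)
  })
  hits <- bind_rows(empty, purrr::compact(per_pattern))

  e_hit <- stringr::str_detect(tokens, stringr::regex(e_number_regex))
  if (any(e_hit)) {
    e_tok <- tokens[e_hit]
    hits <- bind_rows(hits, tibble(
      tier = "tier2", class = "e_numbers",
      pattern = stringr::str_extract(e_tok, stringr::regex(e_number_regex)),
      token = e_tok, exempt_category = NA_character_))
  }
  distinct(hits)
}

#' Classify foods into NOVA groups from name plus ingredient list
#'
#' The "branded database" mode. Starting from the name-based class, the
#' ingredient list is screened for processing markers:
#' \itemize{
#'   \item no ingredient list: the record is `excluded_no_ingredients`;
#'   \item any tier 2 (ultra-processing) marker: NOVA4;
#'   \item otherwise a tier 1 (culinary) marker on a minimally processed
#'     (NOVA1) base: NOVA3;
#'   \item otherwise the name-based class stands.
#' }
#' Reclassification is monotone: the ingredient-based class is never lower
#' than the name-based class, and NOVA1 to NOVA3 is the only promotion that
#' does not end in NOVA4. A name-based NOVA4 is sticky (e.g. packaged bread
#' stays NOVA4 whatever its ingredients).
#'
#' @param foods A food table.
#' @param name_results Result of [classify_by_name()] on the same records.
#' @param lexicon A marker lexicon (default: packaged).
#' @return A tibble shaped like the name result, with `mode =
#'   "by_ingredients"`, `status` in `classified`/`unclassified`/
#'   `excluded_no_ingredients`, and marker hits in `evidence`.
#' @export
classify_by_ingredients <- function(foods, name_results,
                                    lexicon = default_marker_lexicon()) {
  foods <- as_tibble(foods)
  if (is.null(name_results) || !all(foods$record_id %in% name_results$record_id)) {
    abort("`name_results` must cover every record in `foods`.")
  }
  name_idx <- match(foods$record_id, name_results$record_id)
  base_group <- nova_int(name_results$nova_group[name_idx])
  category <- foods$category %||% rep(NA_character_, nrow(foods))

  # tokenize once, then match the lexicon against the unique vocabulary
  token_lists <- purrr::map(foods$ingredient_text, tokenize_ingredients)
  vocab_hits <- marker_hits_for_tokens(unique(unlist(token_lists)), lexicon)

  rows <- purrr::pmap(
    list(token_lists, foods$ingredient_text, category, base_group),
    function(tokens, ing_text, cat, base) {
      if (is.na(ing_text) || trimws(ing_text) == "") {
        return(list(status = "excluded_no_ingredients", group = NA_integer_,
                    evidence = tibble(tier = character(), class = character(),
                                      pattern = character(), token = character())))
      }
      hits <- vocab_hits[vocab_hits$token %in% tokens, ]
      exempt <- !is.na(hits$exempt_category) & hits$exempt_category == cat
      hits <- select(hits[!exempt, ], "tier", "class", "pattern", "token")
      has_tier2 <- any(hits$tier == "tier2")
      has_tier1 <- any(hits$tier == "tier1")
      group <- if (!is.na(base) && base == 4) {
        4L
      } else if (has_tier2) {
        4L
      } else if (has_tier1 && !is.na(base) && base == 1) {
        3L
      } else {
        base
      }
      list(status = if (is.na(group)) "unclassified" else "classified",
           group = group, evidence = hits)
    }
  )
  tibble(
    record_id = foods$record_id,
    mode = "by_ingredients",
    status = purrr::map_chr(rows, "status"),
    nova_group = nova_label(purrr::map_int(rows, "group")),
    evidence = purrr::map(rows, "evidence")
  )
}
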