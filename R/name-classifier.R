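#' Normalize a product name for lexicon matching
#'
#' Lowercases, strips punctuation, folds common spelling variants
#' (yoghurt/yogurt, flavour/flavor, fibre/fiber, ...), and collapses
#' whitespace. When a long name is given it is appended to the product name
#' before normalization, since both carry classification-relevant terms.
#'
#' @param product_name Product name as printed on pack; must be non-empty.
#' @param long_name Optional longer description; concatenated when present.
#' @return A normalized, whitespace-separated token string.
#' @export
#' @examples
#' normalize_name("Greek YOGHURT 2%")           # "greek yogurt 2"
#' normalize_name("Fruit-Yogurt, strawberry")   # "fruit yogurt strawberry"
normalize_name <- function(product_name, long_name = NULL) {
  if (length(product_name) != 1 || is.na(product_name) ||
      trimws(product_name) == "") {
    abort("`product_name` must be a non-empty string.")
  }
  text <- product_name
  if (!is.null(long_name) && length(long_name) == 1 && !is.na(long_name) &&
      trimws(long_name) != "") {
    text <- paste(product_name, long_name)
  }
  text <- tolower(text)
  text <- stringr::str_replace_all(text, "[^a-z0-9]+", " ")
  text <- stringr::str_squish(text)
  fold_spelling(text)
}

# British -> American spelling folds applied token-wise
spelling_variants <- c(
  yoghurt = "yogurt", yoghurts = "yogurts",
  flavour = "flavor", flavours = "flavors",
  flavoured = "flavored", flavouring = "flavoring",
  flavourings = "flavorings",
  fibre = "fiber", colour = "color", coloured = "colored",
  sulphur = "sulfur", sulphite = "sulfite", sulphites = "sulfites",
  caramelised = "caramelized", pasteurised = "pasteurized"
)

fold_spelling <- function(text) {
  tokens <- strsplit(text, " ", fixed = TRUE)[[1]]
  hit <- tokens %in% names(spelling_variants)
  tokens[hit] <- spelling_variants[tokens[hit]]
  paste(tokens, collapse = " ")
}

# pattern-by-text logical match matrix; texts and patterns both normalized
pattern_match_matrix <- function(texts, patterns) {
  m <- matrix(FALSE, nrow = length(texts), ncol = length(patterns),
              dimnames = list(NULL, patterns))
  for (p in patterns) {
    m[, p] <- stringr::str_detect(texts, stringr::regex(phrase_regex(p)))
  }
  m
}

# evaluate the rule cascade for one text given its row of the match matrix
classify_one_name <- function(hit, category, lexicon) {
  for (g in 4:1) {
    idx <- which(lexicon$nova_group == g)
    for (i in idx) {
      scope <- lexicon$category_scope[[i]]
      if (length(scope) > 0 && !(tolower(category %||% "") %in% scope)) next
      req <- lexicon$required[[i]]
      if (length(req) > 0 && !all(hit[req])) next
      any_t <- lexicon$any[[i]]
      any_hits <- character(0)
      if (length(any_t) > 0) {
        h <- hit[any_t]
        if (!any(h)) next
        any_hits <- any_t[h]
      }
      forb <- lexicon$forbidden[[i]]
      if (length(forb) > 0 && any(hit[forb])) next
      return(list(group = g,
                  evidence = tibble(rule_id = lexicon$rule_id[i],
                                    matched_text = c(req, any_hits))))
    }
  }
  list(group = NA_integer_, evidence = tibble(rule_id = character(),
                                              matched_text = character()))
}

#' Classify foods into NOVA groups from the product name alone
#'
#' The "generic database" mode: only the product name (and long name, when
#' present) is consulted, through a lexicon of indicative terms. Rules are
#' evaluated in precedence order NOVA4, NOVA3, NOVA2, NOVA1 — more-processed
#' patterns are tested first because minimally processed entries carry
#' negative qualifiers ("without sugar") that the forbidden-term lists
#' implement. Names matching no rule are reported `unclassified`, never
#' silently defaulted.
#'
#' @param foods A food table (see [validate_food_table()]).
#' @param lexicon A name lexicon; defaults to the packaged transcription of
#'   the indicative-term table.
#' @return A tibble with one row per record: `record_id`, `mode`
#'   (`"by_name"`), `status` (`classified`/`unclassified`), `nova_group`
#'   (factor NOVA1-NOVA4 or `NA`), and an `evidence` list-column of
#'   (rule_id, matched_text) pairs.
#' @export
classify_by_name <- function(foods, lexicon = default_name_lexicon()) {
  foods <- as_tibble(foods)
  lexicon <- validate_name_lexicon(lexicon)
  long_name <- foods$long_name %||% rep(NA_character_, nrow(foods))
  category <- foods$category %||% rep(NA_character_, nrow(foods))
  norms <- purrr::map2_chr(foods$product_name, long_name, normalize_name)

  # classify each distinct (normalized name, category) pair once
  key <- paste(norms, category, sep = "\r")
  first <- !duplicated(key)
  patterns <- unique(unlist(c(lexicon$required, lexicon$any,
                              lexicon$forbidden)))
  m <- pattern_match_matrix(norms[first], patterns)
  res_u <- purrr::map(seq_len(sum(first)), function(i) {
    classify_one_name(m[i, ], category[first][i], lexicon)
  })
  res <- res_u[match(key, key[first])]

  groups <- purrr::map_int(res, "group")
  tibble(
    record_id = foods$record_id,
    mode = "by_name",
    status = if_else(is.na(groups), "unclassified", "classified"),
    nova_group = nova_label(groups),
    evidence = purrr::map(res, "evidence")
  )
}
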