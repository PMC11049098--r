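#' Run the full dual-mode classification and profiling pipeline
#'
#' Classifies every record by name and by name + ingredient list, scores and
#' grades it, cross-tabulates the classification flows, computes fold
#' changes and group shares, per-NOVA nutrient summaries with
#' Kruskal-Wallis tests, and Nutri-Score grade distributions per NOVA group
#' and per reclassification stratum (NOVA4 reached from a NOVA1 name, from
#' a NOVA3 name, or already NOVA4 "generic" by name).
#'
#' All randomness lives in the synthetic generator; the pipeline itself is
#' deterministic.
#'
#' @param foods A validated food table.
#' @param name_lexicon,marker_lexicon Lexicons (default: packaged).
#' @param preset Nutri-Score preset, `"paper"` or `"fsam2017_full"`.
#' @param output_dir Optional directory; when given, every report table is
#'   written there as CSV together with a small run log.
#' @return An object of class `nova_run_report` (a named list of tibbles;
#'   see Details).
#' @details The report contains `input_summary`, `name_results`,
#'   `ingredient_results`, `scores`, `flow` (a `reclass_flow`),
#'   `fold_changes`, `shares`, `nutrient_summaries`, `kw_tests`,
#'   `grade_by_group`, and `grade_by_stratum`.
#' @export
run_pipeline <- function(foods,
                         name_lexicon = default_name_lexicon(),
                         marker_lexicon = default_marker_lexicon(),
                         preset = c("paper", "fsam2017_full"),
                         output_dir = NULL) {
  preset <- arg_match(preset)
  foods <- as_tibble(foods)

  name_res <- classify_by_name(foods, name_lexicon)
  ing_res <- classify_by_ingredients(foods, name_res, marker_lexicon)
  scores <- score_table(foods, preset = preset)
  flow <- crosstab_flows(name_res, ing_res)

  n <- nrow(foods)
  input_summary <- tibble(
    n = n,
    classified_by_name = sum(name_res$status == "classified"),
    unclassified_by_name = sum(name_res$status == "unclassified"),
    classified_by_ingredients = sum(ing_res$status == "classified"),
    unclassified_by_ingredients = sum(ing_res$status == "unclassified"),
    excluded_no_ingredients = sum(ing_res$status == "excluded_no_ingredients"),
    scored = sum(scores$status == "scored"),
    excluded_missing_negative =
      sum(scores$status == "excluded_missing_negative")
  )

  fold_changes <- tibble(
    nova_group = nova_levels(),
    fold_change = purrr::map_dbl(1:4, ~ suppressWarnings(fold_change(flow, .x))),
    percent_increase = purrr::map_dbl(1:4, ~ percent_increase(flow, .x)),
    reclassified_share = purrr::map_dbl(1:4, ~ reclassified_share(flow, .x))
  )
  shares <- tidyr::expand_grid(nova_group = nova_levels(),
                               mode = c("by_name", "by_ingredients")) %>%
    mutate(share = purrr::map2_dbl(.data$nova_group, .data$mode,
                                   ~ nova_share(flow, .x, .y)))

  # nutrient summaries and tests across by-ingredient NOVA groups
  joined <- foods %>%
    left_join(select(ing_res, "record_id", ing_group = "nova_group"),
              by = "record_id") %>%
    left_join(select(name_res, "record_id", name_group = "nova_group"),
              by = "record_id") %>%
    left_join(select(scores, "record_id", "fsam_nps", "grade",
                     score_status = "status"),
              by = "record_id")
  classified <- filter(joined, !is.na(.data$ing_group))
  nutrient_summaries <- summarize_groups(
    classified, .data$ing_group,
    vars = intersect(c("energy_kj", "protein_g", "sfa_g", "sugars_g",
                       "sodium_mg"), names(classified)))
  kw_vars <- c("energy_kj", "protein_g", "sfa_g", "sugars_g", "sodium_mg",
               "fsam_nps")
  kw_tests <- purrr::map(kw_vars, function(v) {
    dat <- classified[!is.na(classified[[v]]), c(v, "ing_group")]
    dat$ing_group <- droplevels(as.factor(dat$ing_group))
    if (nlevels(dat$ing_group) < 2 || nrow(dat) < 4) return(NULL)
    kruskal_wallis(dat, !!sym(v), .data$ing_group) %>%
      mutate(variable = v, .before = 1)
  }) %>% purrr::compact() %>% bind_rows()

  graded <- filter(joined, .data$score_status == "scored",
                   !is.na(.data$grade))
  grade_by_group <- grade_distribution(
    filter(graded, !is.na(.data$ing_group)), .data$ing_group)
  strata <- graded %>%
    filter(!is.na(.data$ing_group), .data$ing_group == "NOVA4") %>%
    mutate(stratum = case_when(
      name_group == "NOVA1" ~ "NOVA4 from NOVA1",
      name_group == "NOVA2" ~ "NOVA4 from NOVA2",
      name_group == "NOVA3" ~ "NOVA4 from NOVA3",
      name_group == "NOVA4" ~ "NOVA4 generic",
      .default = "NOVA4 from unclassified"
    ))
  grade_by_stratum <- grade_distribution(strata, .data$stratum)

  report <- structure(
    list(input_summary = input_summary,
         name_results = name_res,
         ingredient_results = ing_res,
         scores = scores,
         flow = flow,
         fold_changes = fold_changes,
         shares = shares,
         nutrient_summaries = nutrient_summaries,
         kw_tests = kw_tests,
         grade_by_group = grade_by_group,
         grade_by_stratum = grade_by_stratum,
         preset = preset),
    class = "nova_run_report"
  )
  if (!is.null(output_dir)) write_run_report(report, output_dir)
  report
}

#' Write a pipeline report to a directory of CSV files
#'
#' @param report A `nova_run_report`.
#' @param output_dir Directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_run_report <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) {
    readr::write_csv(x, file.path(output_dir, paste0(name, ".csv")), na = "")
  }
  w(report$input_summary, "input_summary")
  w(select(report$name_results, -"evidence"), "classification_by_name")
  w(select(report$ingredient_results, -"evidence"),
    "classification_by_ingredients")
  w(mutate(report$scores,
           imputed_positives = purrr::map_chr(
             .data$imputed_positives, paste, collapse = "|")), "scores")
  w(tidy_flow(report$flow), "flow_table")
  w(report$fold_changes, "fold_changes")
  w(report$shares, "shares")
  w(report$nutrient_summaries, "nutrient_summaries")
  if (nrow(report$kw_tests) > 0) w(report$kw_tests, "kruskal_wallis_tests")
  w(report$grade_by_group, "grade_distribution_by_group")
  w(report$grade_by_stratum, "grade_distribution_by_stratum")
  log_lines <- c(
    paste0("novascore version: ",
           as.character(utils::packageVersion("novascore"))),
    paste0("preset: ", report$preset),
    paste0("n: ", report$input_summary$n),
    paste0("excluded_no_ingredients: ",
           report$input_summary$excluded_no_ingredients),
    paste0("excluded_missing_negative: ",
           report$input_summary$excluded_missing_negative),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  )
  writeLines(log_lines, file.path(output_dir, "run_log.txt"))
  invisible(output_dir)
}

#' @export
print.nova_run_report <- function(x, ...) {
  s <- x$input_summary
  cat("NOVA dual-mode classification report\n")
  cat("  records:", s$n, "\n")
  cat("  by name: ", s$classified_by_name, " classified, ",
      s$unclassified_by_name, " unclassified\n", sep = "")
  cat("  by ingredients: ", s$classified_by_ingredients, " classified, ",
      s$unclassified_by_ingredients, " unclassified, ",
      s$excluded_no_ingredients, " excluded (no ingredient list)\n", sep = "")
  cat("  scored: ", s$scored, " (", s$excluded_missing_negative,
      " excluded for missing negative nutrients)\n", sep = "")
  fc <- x$fold_changes$fold_change[x$fold_changes$nova_group == "NOVA4"]
  cat("  NOVA4 fold change (by ingredients / by name):", fc, "\n")
  invisible(x)
}

#' @export
print.reclass_flow <- function(x, ...) {
  cat("NOVA reclassification flows (rows: by name; columns: by ingredients)\n")
  print(x$counts)
  cat("excluded (no ingredient list):", x$excluded,
      "| unclassified:", x$unclassified, "\n")
  invisible(x)
}
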