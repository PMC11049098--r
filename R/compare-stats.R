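#' Cross-tabulate NOVA classification flows between the two modes
#'
#' Counts every (by-name group, by-ingredient group) pair among records
#' classified in both modes. Records excluded at the ingredient stage (no
#' ingredient list) and records unclassified in either mode are tallied
#' separately; the by-name groups of excluded records are retained so that
#' by-name shares can use the full classified-by-name denominator.
#'
#' @param name_results Result of [classify_by_name()].
#' @param ingredient_results Result of [classify_by_ingredients()] on the
#'   same records.
#' @return An object of class `reclass_flow`: a list with `counts` (4x4
#'   integer matrix, rows = by-name, columns = by-ingredients), `excluded`,
#'   `unclassified`, and `excluded_by_name` (by-name group tallies of the
#'   excluded records).
#' @export
crosstab_flows <- function(name_results, ingredient_results) {
  if (!setequal(name_results$record_id, ingredient_results$record_id)) {
    abort("The two classification results must cover the same record_ids.")
  }
  m <- left_join(
    select(name_results, "record_id", name_group = "nova_group"),
    select(ingredient_results, "record_id", ing_group = "nova_group",
           ing_status = "status"),
    by = "record_id"
  )
  excluded <- m$ing_status == "excluded_no_ingredients"
  both <- !excluded & !is.na(m$name_group) & !is.na(m$ing_group)
  counts <- table(
    factor(m$name_group[both], levels = nova_levels()),
    factor(m$ing_group[both], levels = nova_levels())
  )
  counts <- matrix(as.integer(counts), 4, 4,
                   dimnames = list(by_name = nova_levels(),
                                   by_ingredients = nova_levels()))
  excl_by_name <- table(factor(m$name_group[excluded], levels = nova_levels()))
  structure(
    list(counts = counts,
         excluded = sum(excluded),
         unclassified = sum(!excluded & !both),
         excluded_by_name = setNames(as.integer(excl_by_name), nova_levels())),
    class = "reclass_flow"
  )
}

#' Build a flow table directly from per-record group assignments
#'
#' Convenience constructor for planted or published classifications: takes
#' two vectors of group labels (1-4, `NA` = unclassified, `"excluded"`
#' allowed in `by_ingredients`) and returns the same `reclass_flow` object
#' as [crosstab_flows()].
#'
#' @param by_name,by_ingredients Vectors of equal length with entries in
#'   1-4 / "NOVA1"-"NOVA4"; `by_ingredients` may contain `"excluded"`.
#' @return A `reclass_flow` object.
#' @export
flow_from_assignments <- function(by_name, by_ingredients) {
  stopifnot(length(by_name) == length(by_ingredients))
  canon <- function(x) {
    x <- as.character(x)
    if_else(x %in% as.character(1:4), paste0("NOVA", x), x)
  }
  bn <- canon(by_name)
  bi <- canon(by_ingredients)
  n <- length(bn)
  name_res <- tibble(
    record_id = paste0("r", seq_len(n)), mode = "by_name",
    status = if_else(bn %in% nova_levels(), "classified", "unclassified"),
    nova_group = factor(bn, levels = nova_levels()),
    evidence = vector("list", n)
  )
  ing_res <- tibble(
    record_id = paste0("r", seq_len(n)), mode = "by_ingredients",
    status = case_when(
      bi %in% nova_levels() ~ "classified",
      !is.na(bi) & bi == "excluded" ~ "excluded_no_ingredients",
      .default = "unclassified"
    ),
    nova_group = factor(bi, levels = nova_levels()),
    evidence = vector("list", n)
  )
  crosstab_flows(name_res, ing_res)
}

flow_margins <- function(flow, mode = c("by_name", "by_ingredients")) {
  mode <- arg_match(mode)
  if (mode == "by_name") rowSums(flow$counts) else colSums(flow$counts)
}

#' Fold change in a NOVA group between classification modes
#'
#' Ratio of the by-ingredients group total to the by-name group total among
#' records classified in both modes, reported to 1 decimal.
#'
#' @param flow A `reclass_flow` object.
#' @param group NOVA group, 1-4 or "NOVA1"-"NOVA4".
#' @return Fold change (by-ingredients / by-name), rounded to 1 decimal.
#' @export
fold_change <- function(flow, group) {
  g <- if (is.numeric(group)) paste0("NOVA", group) else as.character(group)
  row_total <- flow_margins(flow, "by_name")[[g]]
  col_total <- flow_margins(flow, "by_ingredients")[[g]]
  if (row_total == 0) {
    warn(paste0("By-name total for ", g, " is zero; fold change undefined."))
    return(NA_real_)
  }
  round(col_total / row_total, 1)
}

#' Share of a NOVA group in each classification mode
#'
#' Percentage of classified records assigned to a group. The by-name
#' denominator includes records later excluded at the ingredient stage
#' (they were classified by name); the by-ingredients denominator covers
#' records classified in both modes.
#'
#' @inheritParams fold_change
#' @param mode `"by_name"` or `"by_ingredients"`.
#' @return Percentage, rounded to 1 decimal.
#' @export
nova_share <- function(flow, group, mode = c("by_name", "by_ingredients")) {
  mode <- arg_match(mode)
  g <- if (is.numeric(group)) paste0("NOVA", group) else as.character(group)
  if (mode == "by_name") {
    num <- flow_margins(flow, "by_name")[[g]] + flow$excluded_by_name[[g]]
    den <- sum(flow$counts) + flow$excluded
  } else {
    num <- flow_margins(flow, "by_ingredients")[[g]]
    den <- sum(flow$counts)
  }
  round(100 * num / den, 1)
}

#' Share of a by-name group reclassified away by the ingredient screen
#'
#' Percentage of a group's by-name records (classified in both modes) whose
#' by-ingredients class differs, i.e. (row total - diagonal) / row total.
#'
#' @inheritParams fold_change
#' @return Percentage, rounded to 1 decimal.
#' @export
reclassified_share <- function(flow, group) {
  g <- if (is.numeric(group)) paste0("NOVA", group) else as.character(group)
  row_total <- flow_margins(flow, "by_name")[[g]]
  if (row_total == 0) return(NA_real_)
  round(100 * (row_total - flow$counts[g, g]) / row_total, 1)
}

#' Percent increase of a NOVA group's count between modes
#'
#' @inheritParams fold_change
#' @return Percentage change (by-ingredients vs by-name), rounded to 1
#'   decimal.
#' @export
percent_increase <- function(flow, group) {
  g <- if (is.numeric(group)) paste0("NOVA", group) else as.character(group)
  row_total <- flow_margins(flow, "by_name")[[g]]
  col_total <- flow_margins(flow, "by_ingredients")[[g]]
  if (row_total == 0) return(NA_real_)
  round(100 * (col_total - row_total) / row_total, 1)
}

#' Pearson chi-square test on a contingency table
#'
#' No continuity correction at any table size, for consistency across table
#' shapes.
#'
#' @param tab An r x c matrix of counts with positive margins.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("Chi-square requires positive row and column margins.")
  }
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = unname(res$p.value))
}

#' Kruskal-Wallis test across k groups
#'
#' Rank-based H with tie correction, df = k - 1.
#'
#' @param data A data frame.
#' @param value Column with the continuous variable (tidy-eval).
#' @param group Column with the grouping variable (tidy-eval).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n_groups`.
#' @export
kruskal_wallis <- function(data, value, group) {
  v <- pull(data, {{ value }})
  g <- as.factor(pull(data, {{ group }}))
  g <- droplevels(g)
  if (nlevels(g) < 2) abort("Kruskal-Wallis needs at least 2 groups.")
  if (any(table(g) == 0)) abort("Every group must be non-empty.")
  res <- kruskal.test(v, g)
  tibble(statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = unname(res$p.value), n_groups = nlevels(g))
}

#' Pairwise Mann-Whitney U tests with Bonferroni correction
#'
#' Tests every unordered pair of groups. Exact p-values are used for small
#' tie-free samples (combined n <= 20), the normal approximation with tie
#' and continuity correction otherwise. Adjusted p is `min(1, p * n_pairs)`.
#'
#' @param data A data frame.
#' @param value,group Columns with the continuous and grouping variable
#'   (tidy-eval).
#' @param alpha Significance threshold applied to the adjusted p (default
#'   0.05).
#' @return Tibble with one row per pair: `group1`, `group2`, `statistic`
#'   (U for `group1`), `p_value`, `p_adjusted`, `significant`.
#' @export
pairwise_mwu_bonferroni <- function(data, value, group, alpha = 0.05) {
  v <- pull(data, {{ value }})
  g <- as.factor(pull(data, {{ group }}))
  g <- droplevels(g)
  lev <- levels(g)
  if (length(lev) < 2) abort("Need at least 2 groups.")
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  n_pairs <- length(pairs)
  rows <- purrr::map(pairs, function(p) {
    x <- v[g == p[1]]
    y <- v[g == p[2]]
    exact <- (length(x) + length(y)) <= 20 && !any(duplicated(c(x, y)))
    res <- suppressWarnings(
      wilcox.test(x, y, exact = exact, correct = TRUE))
    tibble(group1 = p[1], group2 = p[2],
           statistic = unname(res$statistic), p_value = unname(res$p.value))
  })
  bind_rows(rows) %>%
    mutate(p_adjusted = pmin(1, .data$p_value * n_pairs),
           significant = .data$p_adjusted < alpha)
}

#' Per-group nutrient summaries as median (Q1, Q3)
#'
#' Quantiles use linear interpolation (type 7).
#'
#' @param data A data frame.
#' @param group Grouping column (tidy-eval).
#' @param vars Character vector of numeric columns to summarize; defaults to
#'   the nutrient panel columns present in `data`.
#' @return Tibble with one row per group x variable: `n`, `median`, `q1`,
#'   `q3` (all `NA` for empty groups, which are still reported).
#' @export
summarize_groups <- function(data, group, vars = NULL) {
  if (is.null(vars)) {
    vars <- intersect(nutrient_columns(), names(data))
  }
  g <- as.factor(pull(data, {{ group }}))
  purrr::map(vars, function(v) {
    vals <- data[[v]]
    purrr::map(levels(g), function(lv) {
      x <- vals[!is.na(g) & g == lv & !is.na(vals)]
      if (length(x) == 0) {
        tibble(group = lv, variable = v, n = 0L, median = NA_real_,
               q1 = NA_real_, q3 = NA_real_)
      } else {
        qs <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
        tibble(group = lv, variable = v, n = length(x), median = qs[2],
               q1 = qs[1], q3 = qs[3])
      }
    }) %>% bind_rows()
  }) %>% bind_rows()
}

#' Nutri-Score grade distribution per group
#'
#' Counts and percentages (to 1 decimal of each group's scored total) of
#' each grade A-E within each group.
#'
#' @param data A data frame with a `grade` column (factor A-E) and a
#'   grouping column.
#' @param group Grouping column (tidy-eval).
#' @return Tibble: `group`, `grade`, `n`, `pct`.
#' @export
grade_distribution <- function(data, group) {
  g <- as.factor(pull(data, {{ group }}))
  grade <- factor(data$grade, levels = c("A", "B", "C", "D", "E"))
  keep <- !is.na(g) & !is.na(grade)
  if (!any(keep)) {
    return(tibble(group = character(), grade = factor(levels = LETTERS[1:5]),
                  n = integer(), pct = double()))
  }
  tab <- table(group = droplevels(g[keep]), grade = grade[keep])
  out <- as_tibble(tab, .name_repair = "minimal")
  names(out) <- c("group", "grade", "n")
  out %>%
    group_by(.data$group) %>%
    mutate(pct = round(100 * .data$n / sum(.data$n), 1)) %>%
    ungroup() %>%
    mutate(n = as.integer(.data$n))
}

#' Combined A+B share of a grade distribution
#'
#' Percentage of a group's scored records graded A or B, computed from raw
#' counts and rounded to 1 decimal.
#'
#' @param dist Output of [grade_distribution()].
#' @param group Group label to extract.
#' @return Percentage.
#' @export
ab_share <- function(dist, group) {
  rows <- dist[dist$group == group, ]
  if (nrow(rows) == 0 || sum(rows$n) == 0) return(NA_real_)
  round(100 * sum(rows$n[rows$grade %in% c("A", "B")]) / sum(rows$n), 1)
}
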