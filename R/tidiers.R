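#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

tidy_flow <- function(x) {
  as_tibble(x$counts, rownames = "by_name") %>%
    tidyr::pivot_longer(-"by_name", names_to = "by_ingredients",
                        values_to = "n") %>%
    mutate(n = as.integer(.data$n))
}

#' Tidy a reclassification flow table
#'
#' @param x A `reclass_flow` object.
#' @param ... Unused.
#' @return A long tibble with `by_name`, `by_ingredients`, `n`.
#' @method tidy reclass_flow
#' @export
tidy.reclass_flow <- function(x, ...) {
  tidy_flow(x)
}

#' One-row summary of a reclassification flow table
#'
#' @param x A `reclass_flow` object.
#' @param ... Unused.
#' @return A one-row tibble: totals, exclusions, and the NOVA4 fold change
#'   and shares.
#' @method glance reclass_flow
#' @export
glance.reclass_flow <- function(x, ...) {
  tibble(
    n_classified_both = sum(x$counts),
    excluded = x$excluded,
    unclassified = x$unclassified,
    nova4_fold_change = suppressWarnings(fold_change(x, 4)),
    nova4_share_by_name = nova_share(x, 4, "by_name"),
    nova4_share_by_ingredients = nova_share(x, 4, "by_ingredients")
  )
}

#' Tidy a pipeline report
#'
#' @param x A `nova_run_report`.
#' @param ... Unused.
#' @return The long flow table with fold changes and shares attached per
#'   by-name group.
#' @method tidy nova_run_report
#' @export
tidy.nova_run_report <- function(x, ...) {
  tidy_flow(x$flow) %>%
    left_join(rename(x$fold_changes, by_name = "nova_group"), by = "by_name")
}

#' One-row summary of a pipeline report
#'
#' @param x A `nova_run_report`.
#' @param ... Unused.
#' @return A one-row tibble combining the input summary with the NOVA4 flow
#'   statistics.
#' @method glance nova_run_report
#' @export
glance.nova_run_report <- function(x, ...) {
  bind_cols(x$input_summary, select(glance(x$flow), -"excluded"))
}
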