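#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_text geom_col
#'   scale_fill_brewer scale_fill_gradient labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Heatmap of NOVA reclassification flows
#'
#' @param object A `reclass_flow` object.
#' @param ... Unused.
#' @return A ggplot: by-name groups on the y axis, by-ingredient groups on
#'   the x axis, tile fill and label = record count.
#' @method autoplot reclass_flow
#' @export
autoplot.reclass_flow <- function(object, ...) {
  d <- tidy_flow(object)
  ggplot(d, aes(x = .data$by_ingredients, y = .data$by_name,
                fill = .data$n)) +
    geom_tile(color = "grey80") +
    geom_text(aes(label = .data$n), size = 3) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = "NOVA group (by ingredients)", y = "NOVA group (by name)",
         fill = "foods",
         title = "Reclassification between classification modes") +
    theme_minimal()
}

#' Grade distribution bars for a pipeline report
#'
#' @param object A `nova_run_report`.
#' @param by `"group"` (per by-ingredient NOVA group) or `"stratum"`
#'   (per NOVA4 reclassification stratum).
#' @param ... Unused.
#' @return A ggplot of Nutri-Score grade shares.
#' @method autoplot nova_run_report
#' @export
autoplot.nova_run_report <- function(object, by = c("group", "stratum"),
                                     ...) {
  by <- arg_match(by)
  d <- if (by == "group") object$grade_by_group else object$grade_by_stratum
  ggplot(d, aes(x = .data$grade, y = .data$pct, fill = .data$grade)) +
    geom_col() +
    facet_wrap(~group) +
    scale_fill_brewer(palette = "RdYlGn", direction = -1) +
    labs(x = "Nutri-Score grade", y = "% of scored foods",
         title = "Nutri-Score grade distribution") +
    theme_minimal()
}

#' Bar chart of a Nutri-Score grade distribution
#'
#' @param dist Output of [grade_distribution()].
#' @return A ggplot with one facet per group.
#' @export
plot_grade_distribution <- function(dist) {
  ggplot(dist, aes(x = .data$grade, y = .data$pct, fill = .data$grade)) +
    geom_col() +
    facet_wrap(~group) +
    scale_fill_brewer(palette = "RdYlGn", direction = -1) +
    labs(x = "Nutri-Score grade", y = "% of scored foods") +
    theme_minimal()
}
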