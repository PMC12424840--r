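# ggplot2 views of the main result types. These reproduce the package's
# standard visual summaries (bubble heatmap, class tallies, druggability
# violins); chord diagrams, Sankeys and network layouts are delegated to
# external tools via the exported link/graph files.

#' Bubble-heatmap of association profiles
#'
#' Compounds by category, point size = number of containing formulas,
#' colour = percentage of those formulas treating the category.
#'
#' @param profiles An `"association_profiles"` tibble.
#' @param max_compounds Cap on displayed compounds (ordered by
#'   `n_formulas`).
#' @return A ggplot object.
#' @export
plot_association_bubbles <- function(profiles, max_compounds = 40) {
  stopifnot(inherits(profiles, "association_profiles"))
  keep <- profiles |>
    distinct(.data$compound_key, .data$n_formulas) |>
    arrange(desc(.data$n_formulas)) |>
    head(max_compounds)
  df <- filter(profiles, .data$compound_key %in% keep$compound_key,
               .data$n_formulas > 0)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$category,
    y = stats::reorder(.data$compound_key, .data$n_formulas),
    size = .data$n_formulas, colour = .data$pct)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c(limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = NULL, size = "formulas (n)",
                  colour = "% treating") +
    ggplot2::theme_minimal()
}

#' @rdname assemble_meta_metabolome
#' @param object A `meta_metabolome` (for `autoplot()`).
#' @method autoplot meta_metabolome
#' @export
autoplot.meta_metabolome <- function(object, ...) {
  df <- mutate(object$class_tally,
               bin = factor(.data$bin, levels = phytochemical_classes()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$n)) +
    ggplot2::geom_col(fill = "seagreen4") +
    ggplot2::labs(x = NULL, y = "compounds",
                  title = sprintf("%s meta-metabolome (%d compounds)",
                                  object$species %||% "", object$total)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Violin plots of druggability metrics across compound sets
#'
#' @param records Druggability record table (see
#'   [druggability_records()]).
#' @param sets Named list of compound-key vectors.
#' @param metric `"wqed"` or `"np_likeness"`.
#' @param band Desirable band drawn as dashed lines.
#' @return A ggplot object.
#' @export
plot_druggability_sets <- function(records, sets,
                                   metric = c("wqed", "np_likeness"),
                                   band = NULL) {
  metric <- match.arg(metric)
  if (is.null(band)) {
    band <- if (metric == "wqed") c(0.4, 0.7) else c(0.5, 2.5)
  }
  df <- bind_rows(imap(sets, function(keys, nm) {
    filter(records, .data$compound_key %in% keys) |>
      mutate(set = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set,
                                   y = .data[[metric]],
                                   fill = .data$set)) +
    ggplot2::geom_violin(trim = FALSE, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = band, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
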