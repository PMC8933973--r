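#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a coverage curve
#'
#' Percent of target proteins covered against the number of top-ranked
#' peptides retained.
#'
#' @param object A `coverage_curve` from [coverage_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coverage_curve <- function(object, ...) {
  fam <- attr(object, "family")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cutoff, y = .data$percent_covered)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = "Top-ranked peptides retained",
                  y = "Target proteins covered (%)",
                  title = if (!is.na(fam)) paste("Coverage curve,", fam)) +
    ggplot2::theme_minimal()
}

#' Plot a ranked peptide cover
#'
#' Bar chart of proteins covered per selected peptide, by rank (the
#' top-ranked peptides capture the large shared groups; the tail covers
#' singletons).
#'
#' @param object A `peptide_cover`.
#' @param top_n Show at most this many ranks (default 25).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.peptide_cover <- function(object, top_n = 25, ...) {
  df <- utils::head(tibble::as_tibble(object)[c("rank", "peptide", "n_proteins")], top_n)
  fam <- attr(object, "family")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$peptide, .data$rank),
                                   y = .data$n_proteins)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Proteins covered",
                  title = if (!is.na(fam)) paste("Top peptides,", fam)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot the per-phylum CAZyme class composition
#'
#' Stacked proportions of CAZyme classes (GH, GT, PL, CE, AA, CBM,
#' cohesin/SLH) per phylum, from a [cazyme_census()] with taxonomy.
#'
#' @param object A `cazyme_census`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cazyme_census <- function(object, ...) {
  if (is.null(object$per_phylum)) {
    abort("Census has no per-phylum rollup (no taxonomy was supplied)")
  }
  ggplot2::ggplot(object$per_phylum,
                  ggplot2::aes(x = .data$phylum, y = .data$proportion,
                               fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Proportion of CAZyme assignments",
                  fill = "CAZyme class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the phylum composition of selected peptides
#'
#' Stacked bars of covered proteins per phylum for the top-ranked selected
#' peptides.
#'
#' @param result A `peptide_cover`.
#' @param proteins Records tibble (`protein_id`, `mag_id`).
#' @param taxonomy Taxonomy tibble (`mag_id`, `phylum`).
#' @param top_n Show at most this many ranks (default 25).
#' @return A ggplot object.
#' @export
plot_phylum_composition <- function(result, proteins, taxonomy, top_n = 25) {
  df <- group_by_phylum(result, proteins, taxonomy) %>%
    dplyr::filter(.data$rank <= top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$peptide, .data$rank),
                                   y = .data$n_proteins, fill = .data$phylum)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Proteins covered", fill = "Phylum") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
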