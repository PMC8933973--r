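#' Consensus CAZyme family assignment from three annotation tools
#'
#' Applies the dbCAN2-recommended consensus rule: only proteins annotated by
#' at least two of HMMER, DIAMOND and Hotpep are considered CAZymes. When
#' HMMER reports a family, its label set wins; when HMMER is empty, the
#' intersection of the DIAMOND and Hotpep label sets is used, and proteins
#' with an empty intersection are discarded.
#'
#' @param rows Annotation tibble from [read_tool_annotations()]
#'   (`protein_id` plus list-columns `hmmer`, `diamond`, `hotpep`).
#' @return A tibble with columns `protein_id`, `family`, `evidence`
#'   (`"hmmer-priority"` or `"diamond-hotpep-agreement"`), one row per
#'   (protein, family) pair, sorted by `protein_id` then `family`. The ids
#'   of discarded proteins are attached as attribute `"discarded"`.
#' @examples
#' rows <- tibble::tibble(
#'   protein_id = c("p1", "p2", "p3"),
#'   hmmer = list("GH13", character(), character()),
#'   diamond = list("GH13", "GH3", "GH3"),
#'   hotpep = list(character(), "GH3", "GH5")
#' )
#' consensus_families(rows)
#' @export
consensus_families <- function(rows) {
  stopifnot(all(c("protein_id", "hmmer", "diamond", "hotpep") %in% names(rows)))
  one <- function(h, d, p) {
    n_tools <- (length(h) > 0) + (length(d) > 0) + (length(p) > 0)
    if (n_tools < 2) return(NULL)
    if (length(h) > 0) {
      return(list(families = sort(unique(h)), evidence = "hmmer-priority"))
    }
    common <- sort(intersect(d, p))
    if (length(common) == 0) return(NULL)
    list(families = common, evidence = "diamond-hotpep-agreement")
  }
  picks <- purrr::pmap(list(rows$hmmer, rows$diamond, rows$hotpep), one)
  kept <- !vapply(picks, is.null, logical(1))
  considered <- lengths(rows$hmmer) + lengths(rows$diamond) + lengths(rows$hotpep) > 0
  discarded <- rows$protein_id[considered & !kept]
  out <- purrr::map2_dfr(rows$protein_id[kept], picks[kept], function(id, pk) {
    tibble::tibble(protein_id = id, family = pk$families, evidence = pk$evidence)
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(protein_id = character(), family = character(),
                          evidence = character())
  }
  out <- dplyr::arrange(out, .data$protein_id, .data$family)
  attr(out, "discarded") <- sort(unique(discarded))
  if (length(discarded) > 0) {
    inform(paste0(length(unique(discarded)),
                  " annotated protein(s) discarded by the consensus rule"))
  }
  out
}

#' CAZyme census of a MAG community
#'
#' Per MAG: proteome size, number of consensus-annotated CAZyme proteins,
#' and the percentage of the proteome they represent. With a taxonomy
#' table, also per phylum: the median CAZyme percentage across its MAGs and
#' the proportion of family assignments falling in each CAZyme class (GH,
#' GT, PL, CE, AA, CBM, cohesin/SLH).
#'
#' @param assignments Consensus assignments from [consensus_families()].
#' @param proteins Records tibble (`protein_id`, `mag_id`, `sequence`) for
#'   the whole community; supplies proteome sizes and the protein-to-MAG map.
#' @param taxonomy Optional taxonomy tibble (`mag_id`, `phylum`).
#' @return A list of class `cazyme_census` with tibbles `per_mag`
#'   (`mag_id`, `n_proteins`, `n_cazymes`, `pct_cazymes`) and `per_phylum`
#'   (`phylum`, `n_mags`, `median_pct_cazymes`, `class`, `proportion`;
#'   `NULL` without taxonomy).
#' @export
cazyme_census <- function(assignments, proteins, taxonomy = NULL) {
  check_records(proteins)
  unknown <- setdiff(assignments$protein_id, proteins$protein_id)
  if (length(unknown) > 0) {
    abort(paste0("Assigned protein(s) not present in the community: ",
                 paste(utils::head(unknown, 5), collapse = ", ")))
  }
  per_mag <- proteins %>%
    dplyr::count(.data$mag_id, name = "n_proteins") %>%
    dplyr::left_join(
      assignments %>%
        dplyr::distinct(.data$protein_id) %>%
        dplyr::left_join(proteins[c("protein_id", "mag_id")], by = "protein_id") %>%
        dplyr::count(.data$mag_id, name = "n_cazymes"),
      by = "mag_id"
    ) %>%
    dplyr::mutate(n_cazymes = tidyr::replace_na(.data$n_cazymes, 0L),
                  pct_cazymes = 100 * .data$n_cazymes / .data$n_proteins) %>%
    dplyr::arrange(.data$mag_id)

  per_phylum <- NULL
  if (!is.null(taxonomy)) {
    mag_phy <- per_mag %>%
      dplyr::left_join(taxonomy, by = "mag_id") %>%
      dplyr::mutate(phylum = tidyr::replace_na(.data$phylum, "NA"))
    med <- mag_phy %>%
      dplyr::group_by(.data$phylum) %>%
      dplyr::summarise(n_mags = dplyr::n(),
                       median_pct_cazymes = stats::median(.data$pct_cazymes),
                       .groups = "drop")
    cls <- assignments %>%
      dplyr::mutate(class = family_class(.data$family)) %>%
      dplyr::distinct(.data$protein_id, .data$class) %>%
      dplyr::left_join(proteins[c("protein_id", "mag_id")], by = "protein_id") %>%
      dplyr::left_join(taxonomy, by = "mag_id") %>%
      dplyr::mutate(phylum = tidyr::replace_na(.data$phylum, "NA")) %>%
      dplyr::count(.data$phylum, .data$class) %>%
      dplyr::group_by(.data$phylum) %>%
      dplyr::mutate(proportion = .data$n / sum(.data$n)) %>%
      dplyr::ungroup() %>%
      dplyr::select(-"n")
    per_phylum <- dplyr::left_join(med, cls, by = "phylum") %>%
      dplyr::arrange(.data$phylum, .data$class)
  }
  structure(list(per_mag = per_mag, per_phylum = per_phylum),
            class = "cazyme_census")
}

#' @export
print.cazyme_census <- function(x, ...) {
  cat("CAZyme census:", nrow(x$per_mag), "MAGs;",
      sum(x$per_mag$n_cazymes), "CAZyme proteins (",
      sprintf("%.2f", 100 * sum(x$per_mag$n_cazymes) / sum(x$per_mag$n_proteins)),
      "% of", sum(x$per_mag$n_proteins), "proteins)\n")
  if (!is.null(x$per_phylum)) {
    cat("Phyla:", paste(unique(x$per_phylum$phylum), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Split a community into target and background protein sets for a family
#'
#' Targets are all proteins whose consensus family set contains the
#' requested family (subfamily suffixes collapsed, so `GH13_20` members are
#' `GH13` targets). The background is every other protein in the community
#' — unannotated proteins and members of other families alike. A
#' multi-family protein is a target for each family it carries and never
#' enters the background of any of them.
#'
#' @param records Community records tibble.
#' @param assignments Consensus assignments from [consensus_families()].
#' @param family A single CAZy family label (e.g. `"GH13"`).
#' @return A list with tibbles `targets` and `background` partitioning
#'   `records`.
#' @export
split_target_background <- function(records, assignments, family) {
  check_records(records)
  if (length(family) != 1 || !is_valid_family(family)) {
    abort(paste0("`family` must be a single valid CAZy family label, got: ",
                 paste(family, collapse = ", ")))
  }
  fam <- collapse_subfamily(family)
  target_ids <- unique(assignments$protein_id[collapse_subfamily(assignments$family) == fam])
  if (length(target_ids) == 0) {
    abort(paste0("No target proteins for family ", family, " in this community"))
  }
  is_target <- records$protein_id %in% target_ids
  list(targets = records[is_target, ], background = records[!is_target, ])
}
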