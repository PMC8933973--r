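#' Family-unique peptides: target peptidome minus the background
#'
#' Keeps the target peptides whose exact tryptic sequence never occurs in
#' the background peptidome. Uniqueness is peptide-level string identity —
#' a target peptide is removed only when the identical tryptic peptide
#' exists in the background, regardless of its context there. Membership
#' sets are unchanged.
#'
#' @param target A filtered target `peptidome`.
#' @param background A raw background `peptidome`.
#' @return A `peptidome` restricted to family-unique peptides (possibly
#'   empty — reported, not an error).
#' @export
unique_target_peptides <- function(target, background) {
  stopifnot(inherits(target, "peptidome"), inherits(background, "peptidome"))
  bg <- unique(background$peptide)
  out <- target[!target$peptide %in% bg, ]
  if (nrow(out) == 0) inform("No family-unique peptides remain after background comparison")
  new_peptidome(tibble::as_tibble(out), provenance = "target",
                filtered = attr(target, "filtered"))
}

new_peptide_cover <- function(tbl, family, total_target_proteins, residual) {
  structure(tbl, class = c("peptide_cover", class(tibble::tibble())),
            family = family,
            total_target_proteins = as.integer(total_target_proteins),
            residual = sort(residual))
}

#' Greedy minimum cover of target proteins by unique peptides
#'
#' Approximates the smallest ranked list of family-unique peptides that
#' jointly cover every coverable target protein. Iteratively selects the
#' peptide mapping to the largest number of not-yet-covered proteins,
#' removes those proteins from every remaining peptide's set, drops
#' peptides whose sets become empty, and repeats until all proteins are
#' covered. Ties are broken by the lexicographically smallest peptide
#' string, making the result independent of input order.
#'
#' @param unique_pep A non-empty `peptidome` of family-unique peptides.
#' @param family Family label to attach to the result.
#' @param total_target_proteins Total number of target proteins (seeds) for
#'   the family, including any with zero unique peptides; defaults to the
#'   number of proteins present in `unique_pep`. Coverage percentages are
#'   relative to this total, and proteins lacking any unique peptide are
#'   reported in the `residual` attribute rather than silently dropped.
#' @param all_protein_ids Optional character vector of every target protein
#'   id, used to populate the residual (uncovered) list.
#' @return A `peptide_cover`: tibble with columns `rank`, `peptide`,
#'   `n_proteins` and list-column `proteins` (the covered ids, pairwise
#'   disjoint across rows, sizes non-increasing with rank), plus
#'   attributes `family`, `total_target_proteins` and `residual`.
#' @examples
#' pep <- tibble::tibble(
#'   peptide = c(rep("PEPTIDEK", 2), "OTHERR"),
#'   protein_id = c("a", "b", "c")
#' )
#' pd <- build_peptidome(tibble::tibble(protein_id = "x", mag_id = "m",
#'                                      sequence = "AAAAAAK"))
#' @export
greedy_min_cover <- function(unique_pep, family = NA_character_,
                             total_target_proteins = NULL,
                             all_protein_ids = NULL) {
  stopifnot(inherits(unique_pep, "peptidome"))
  if (nrow(unique_pep) == 0) abort("`unique_pep` is empty: nothing to cover")
  sets <- split(unique_pep$protein_id, unique_pep$peptide)
  sets <- lapply(sets, unique)
  coverable <- unique(unlist(sets, use.names = FALSE))
  total <- total_target_proteins %||% length(coverable)
  all_ids <- all_protein_ids %||% coverable

  ranks <- list()
  r <- 0L
  while (length(sets) > 0) {
    sizes <- lengths(sets)
    best_size <- max(sizes)
    cand <- names(sets)[sizes == best_size]
    pick <- sort(cand)[1]
    covered <- sort(sets[[pick]])
    r <- r + 1L
    ranks[[r]] <- tibble::tibble(rank = r, peptide = pick,
                                 n_proteins = length(covered),
                                 proteins = list(covered))
    sets[[pick]] <- NULL
    if (length(sets) > 0) {
      sets <- lapply(sets, setdiff, y = covered)
      sets <- sets[lengths(sets) > 0]
    }
  }
  tbl <- dplyr::bind_rows(ranks)
  residual <- setdiff(all_ids, unlist(tbl$proteins, use.names = FALSE))
  new_peptide_cover(tbl, family = family, total_target_proteins = total,
                    residual = residual)
}

#' @export
print.peptide_cover <- function(x, ...) {
  fam <- attr(x, "family")
  cat("<peptide_cover>", if (!is.na(fam)) paste0("family ", fam), "\n")
  cat(" ", nrow(x), "peptides covering", sum(x$n_proteins), "of",
      attr(x, "total_target_proteins"), "target proteins;",
      length(attr(x, "residual")), "uncovered\n")
  NextMethod()
}

#' @describeIn greedy_min_cover Tidy the cover into a plain tibble with
#'   `protein_ids` as a semicolon-joined column.
#' @param x A `peptide_cover`.
#' @param ... Unused.
#' @export
tidy.peptide_cover <- function(x, ...) {
  tibble::tibble(
    rank = x$rank, peptide = x$peptide, n_proteins = x$n_proteins,
    protein_ids = vapply(x$proteins, function(p) paste(sort(p), collapse = ";"),
                         character(1))
  )
}

#' @describeIn greedy_min_cover One-row summary: peptide count, proteins
#'   covered, totals and coverage percentage.
#' @export
glance.peptide_cover <- function(x, ...) {
  total <- attr(x, "total_target_proteins")
  covered <- sum(x$n_proteins)
  tibble::tibble(
    family = attr(x, "family"),
    n_peptides = nrow(x),
    n_proteins_covered = covered,
    total_target_proteins = total,
    pct_covered = if (total > 0) 100 * covered / total else 0,
    max_proteins_per_peptide = if (nrow(x) > 0) max(x$n_proteins) else 0L,
    n_residual = length(attr(x, "residual"))
  )
}

#' Exact minimum cover size by exhaustive search
#'
#' Test oracle for greedy quality: finds the true minimum number of
#' peptides whose sets cover every coverable protein, by exhaustive subset
#' enumeration over bitmask-encoded sets. Refuses instances with more than
#' `max_peptides` distinct peptides.
#'
#' @param unique_pep A `peptidome`.
#' @param max_peptides Refusal threshold (default 15).
#' @return The optimal cover size as an integer.
#' @export
brute_force_min_cover <- function(unique_pep, max_peptides = 15) {
  stopifnot(inherits(unique_pep, "peptidome"))
  sets <- split(unique_pep$protein_id, unique_pep$peptide)
  npep <- length(sets)
  if (npep == 0) return(0L)
  if (npep > max_peptides) {
    abort(paste0("Instance too large for exhaustive search: ", npep,
                 " peptides > max_peptides = ", max_peptides))
  }
  prots <- unique(unlist(sets, use.names = FALSE))
  if (length(prots) > 30) abort("Instance too large: > 30 proteins")
  masks <- vapply(sets, function(s) {
    sum(bitwShiftL(1L, match(unique(s), prots) - 1L))
  }, numeric(1))
  full <- sum(bitwShiftL(1L, seq_along(prots) - 1L))
  for (k in seq_len(npep)) {
    combos <- utils::combn(npep, k)
    for (j in seq_len(ncol(combos))) {
      if (Reduce(bitwOr, masks[combos[, j]]) == full) return(k)
    }
  }
  npep
}

#' Coverage curve: percent of target proteins covered by top-ranked peptides
#'
#' For each cutoff `k`, the percentage of all target proteins covered by
#' the first `k` groups of the ranked selection.
#'
#' @param result A `peptide_cover`.
#' @param cutoffs Positive integer cutoffs (default `c(10, 50, 100, 200)`).
#' @return A `coverage_curve` tibble with columns `cutoff`,
#'   `percent_covered` (non-decreasing in cutoff, bounded by 100).
#' @export
coverage_curve <- function(result, cutoffs = c(10, 50, 100, 200)) {
  stopifnot(inherits(result, "peptide_cover"))
  if (any(cutoffs <= 0)) abort("`cutoffs` must be positive")
  cutoffs <- as.integer(cutoffs)
  total <- attr(result, "total_target_proteins")
  cum <- cumsum(result$n_proteins)
  pct <- vapply(cutoffs, function(k) {
    if (nrow(result) == 0 || total == 0) return(0)
    100 * cum[min(k, length(cum))] / total
  }, numeric(1))
  structure(tibble::tibble(cutoff = cutoffs, percent_covered = pct),
            class = c("coverage_curve", class(tibble::tibble())),
            family = attr(result, "family"))
}

#' Group selected peptides by the EC numbers of their covered proteins
#'
#' Each selected peptide is labelled by the set of distinct EC annotations
#' across the proteins it covers; proteins lacking EC annotation contribute
#' `"N/A"`. Composite keys (a peptide covering proteins of several
#' activities) are kept as the sorted, semicolon-joined set. Peptides and
#' proteins are tallied per distinct EC set.
#'
#' @param result A `peptide_cover`.
#' @param ec_table Long EC table (`protein_id`, `ec`), or `NULL`.
#' @return A tibble with columns `ec_set`, `n_peptides`, `n_proteins`,
#'   sorted by decreasing `n_proteins`.
#' @export
group_by_ec <- function(result, ec_table = NULL) {
  stopifnot(inherits(result, "peptide_cover"))
  key_of <- function(ids) {
    if (is.null(ec_table)) return("N/A")
    sub <- ec_table[ec_table$protein_id %in% ids, ]
    labs <- sort(unique(sub$ec))
    if (length(unique(sub$protein_id)) < length(ids)) labs <- c(labs, "N/A")
    paste(labs, collapse = ";")
  }
  tibble::tibble(
    ec_set = vapply(result$proteins, key_of, character(1)),
    n = result$n_proteins
  ) %>%
    dplyr::group_by(.data$ec_set) %>%
    dplyr::summarise(n_peptides = dplyr::n(), n_proteins = sum(.data$n),
                     .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$n_proteins), .data$ec_set)
}

#' Phylum composition of each selected peptide
#'
#' Counts the covered proteins of every selected peptide per phylum of the
#' MAG they derive from; MAGs unassigned at the phylum level fall in the
#' `"NA"` bucket. A peptide whose proteins all come from one phylum is
#' flagged taxon-specific.
#'
#' @param result A `peptide_cover`.
#' @param proteins Records tibble giving the `protein_id` -> `mag_id` map.
#' @param taxonomy Taxonomy tibble (`mag_id`, `phylum`).
#' @return A tibble with columns `rank`, `peptide`, `phylum`, `n_proteins`,
#'   `taxon_specific` (one row per peptide-phylum pair).
#' @export
group_by_phylum <- function(result, proteins, taxonomy) {
  stopifnot(inherits(result, "peptide_cover"))
  long <- tidyr::unnest_longer(
    tibble::tibble(rank = result$rank, peptide = result$peptide,
                   protein_id = result$proteins),
    "protein_id")
  long$mag_id <- proteins$mag_id[match(long$protein_id, proteins$protein_id)]
  if (any(is.na(long$mag_id))) {
    abort("Covered protein(s) missing from the `proteins` table")
  }
  long$phylum <- taxonomy$phylum[match(long$mag_id, taxonomy$mag_id)]
  long$phylum[is.na(long$phylum)] <- "NA"
  long %>%
    dplyr::count(.data$rank, .data$peptide, .data$phylum, name = "n_proteins") %>%
    dplyr::group_by(.data$rank, .data$peptide) %>%
    dplyr::mutate(taxon_specific = dplyr::n() == 1 & .data$phylum != "NA") %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$rank, .data$phylum)
}

#' Number of ranked peptides needed to cover all proteins of a phylum
#'
#' In `"prefix"` mode (default), returns the smallest prefix length `k` of
#' the family-wide ranked selection such that the first `k` groups contain
#' every covered target protein of the phylum — the convention of reading
#' the counts off the family-wide list, whose groups may mix taxonomic
#' origins. In `"restricted"` mode, the greedy cover is re-run on the
#' unique peptidome restricted to the phylum's proteins (a phylum-specific
#' panel), which can need fewer peptides.
#'
#' @param result A `peptide_cover`.
#' @param proteins Records tibble giving `protein_id` -> `mag_id`.
#' @param taxonomy Taxonomy tibble (`mag_id`, `phylum`).
#' @param phylum Phylum name.
#' @param mode `"prefix"` or `"restricted"`.
#' @param unique_pep The family-unique `peptidome`; required for
#'   `"restricted"` mode.
#' @return Integer count; 0 when the phylum has no covered target protein.
#' @export
peptides_to_cover_taxon <- function(result, proteins, taxonomy, phylum,
                                    mode = c("prefix", "restricted"),
                                    unique_pep = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(result, "peptide_cover"))
  mags <- taxonomy$mag_id[taxonomy$phylum == phylum]
  phy_prots <- proteins$protein_id[proteins$mag_id %in% mags]
  covered_phy <- intersect(unlist(result$proteins, use.names = FALSE), phy_prots)
  if (length(covered_phy) == 0) return(0L)
  if (mode == "prefix") {
    hit_rank <- vapply(covered_phy, function(p) {
      result$rank[vapply(result$proteins, function(s) p %in% s, logical(1))][1]
    }, numeric(1))
    return(as.integer(max(hit_rank)))
  }
  if (is.null(unique_pep)) {
    abort("`unique_pep` is required for mode = \"restricted\"")
  }
  sub <- unique_pep[unique_pep$protein_id %in% phy_prots, ]
  if (nrow(sub) == 0) return(0L)
  sub <- new_peptidome(tibble::as_tibble(sub), provenance = "target",
                       filtered = attr(unique_pep, "filtered"))
  nrow(greedy_min_cover(sub, family = attr(result, "family")))
}
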