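#' Deduplicate protein sequences at 100% identity
#'
#' Removes exact duplicate sequences and any sequence that is a contiguous
#' substring of a longer retained sequence, mirroring CD-HIT clustering at
#' 100% identity (used to drop partial or fragmented gene calls before
#' peptide selection). Each cluster is represented by its longest member;
#' ties go to the lexicographically smallest `protein_id`.
#'
#' @param records Records tibble (`protein_id`, `mag_id`, `sequence`).
#' @return The retained representative rows, in the original column layout.
#' @examples
#' recs <- tibble::tibble(protein_id = c("p1", "p2"), mag_id = "m",
#'                        sequence = c("ABCDEFGH", "CDEF"))
#' dedup_100(recs)
#' @export
dedup_100 <- function(records) {
  check_records(records)
  if (nrow(records) == 0) abort("`records` must be non-empty")
  ord <- order(-nchar(records$sequence), records$protein_id)
  recs <- records[ord, ]
  keep <- logical(nrow(recs))
  kept_seqs <- character(0)
  for (i in seq_len(nrow(recs))) {
    s <- recs$sequence[i]
    contained <- length(kept_seqs) > 0 &&
      any(stringr::str_detect(kept_seqs, stringr::fixed(s)))
    if (!contained) {
      keep[i] <- TRUE
      kept_seqs <- c(kept_seqs, s)
    }
  }
  out <- recs[keep, ]
  out[order(match(out$protein_id, records$protein_id)), ]
}

#' Trim the N-terminus of protein sequences
#'
#' Removes the first `n` residues of each sequence — the positional
#' surrogate for signal-peptide removal, so peptide candidates are not
#' drawn from maturation regions cleaved off in vivo. Sequences of length
#' `<= n` become empty strings (they contribute no peptides).
#'
#' @param seq Character vector of amino-acid sequences.
#' @param n Number of N-terminal residues to remove (default 24).
#' @return Character vector of trimmed sequences.
#' @export
trim_n_terminus <- function(seq, n = 24) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 0)
  substring(seq, n + 1)
}

#' In silico tryptic digestion of one sequence
#'
#' Cleaves after every lysine (K) or arginine (R) that is not immediately
#' followed by proline (P) — classic trypsin specificity, zero missed
#' cleavages, as implemented by Unipept's `prot2pept`. Concatenating the
#' output reproduces the input exactly.
#'
#' @param seq A single uppercase amino-acid string.
#' @return Ordered character vector of tryptic peptides (possibly length 0
#'   for an empty input).
#' @examples
#' tryptic_digest("AAAKGGGRTTT")
#' tryptic_digest("AAAKPGGG")
#' @export
tryptic_digest <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (!nzchar(seq)) return(character(0))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  len <- length(chars)
  is_kr <- chars == "K" | chars == "R"
  next_p <- c(chars[-1] == "P", FALSE)
  cuts <- which(is_kr & !next_p)
  starts <- c(1L, cuts[cuts < len] + 1L)
  ends <- c(cuts[cuts < len], len)
  substring(seq, starts, ends)
}

#' Filter tryptic peptides by the empirical targeted-proteomics rules
#'
#' Retains peptides of 6–25 residues containing neither methionine nor
#' cysteine (residues prone to artifactual modification) and composed only
#' of the 20 canonical amino acids; peptides spanning ambiguous residues
#' (X, B, Z, U) or stops are dropped.
#'
#' @param peps Character vector of peptides.
#' @param min_len,max_len Inclusive length bounds (defaults 6 and 25).
#' @param excluded_residues Residues that disqualify a peptide
#'   (default `c("M", "C")`).
#' @return The retained peptides, in input order.
#' @export
filter_peptides <- function(peps, min_len = 6, max_len = 25,
                            excluded_residues = c("M", "C")) {
  stopifnot(min_len > 0, max_len >= min_len)
  if (length(peps) == 0) return(character(0))
  len_ok <- nchar(peps) >= min_len & nchar(peps) <= max_len
  canon <- grepl(paste0("^[", paste(AA20, collapse = ""), "]+$"), peps)
  excl_ok <- if (length(excluded_residues) > 0) {
    !grepl(paste0("[", paste(excluded_residues, collapse = ""), "]"), peps)
  } else TRUE
  peps[len_ok & canon & excl_ok]
}

new_peptidome <- function(tbl, provenance, filtered) {
  structure(tbl, class = c("peptidome", class(tibble::tibble())),
            provenance = provenance, filtered = filtered)
}

#' Construct a peptidome from a peptide-membership table
#'
#' For bringing externally computed peptide-to-protein memberships into the
#' selection functions: a long table of `(peptide, protein_id)` pairs
#' becomes a `peptidome` object.
#'
#' @param df Data frame with columns `peptide` and `protein_id`.
#' @param provenance `"target"` or `"background"`.
#' @param filtered Whether the peptides have already passed
#'   [filter_peptides()].
#' @return A `peptidome`.
#' @export
as_peptidome <- function(df, provenance = c("target", "background"),
                         filtered = FALSE) {
  provenance <- match.arg(provenance)
  if (!all(c("peptide", "protein_id") %in% names(df))) {
    abort("`df` must have columns peptide and protein_id")
  }
  if (any(!nzchar(df$peptide))) abort("Peptides must be non-empty strings")
  tbl <- dplyr::distinct(tibble::as_tibble(df[c("peptide", "protein_id")])) %>%
    dplyr::arrange(.data$peptide, .data$protein_id)
  new_peptidome(tbl, provenance, isTRUE(filtered))
}

#' @export
print.peptidome <- function(x, ...) {
  cat("<peptidome> ", length(unique(x$peptide)), " peptides over ",
      length(unique(x$protein_id)), " proteins (",
      attr(x, "provenance"), ", ",
      if (isTRUE(attr(x, "filtered"))) "filtered" else "raw", ")\n", sep = "")
  NextMethod()
}

#' Build a peptidome from protein records
#'
#' Digests every record and unions the peptide-to-protein memberships into
#' a long table. The canonical target build is `dedup = TRUE, trim = 24,
#' apply_filter = TRUE`; the canonical background build digests as-is with
#' no trimming and no filtering (an unfiltered background makes uniqueness
#' strictly harder to attain, which is the conservative direction). The
#' [target_peptidome()] / [background_peptidome()] wrappers encode those
#' two recipes.
#'
#' @param records Records tibble; must be non-empty.
#' @param trim Number of N-terminal residues to remove before digestion, or
#'   `NULL` for none.
#' @param apply_filter Apply [filter_peptides()] to the digests?
#' @param dedup Run [dedup_100()] first?
#' @param min_len,max_len,excluded_residues Passed to [filter_peptides()].
#' @param il_equivalence Treat isoleucine and leucine as indistinguishable
#'   (as on a mass spectrometer) by rewriting I to L in every peptide.
#' @param provenance `"target"` or `"background"` tag carried on the object.
#' @return A `peptidome`: tibble with columns `peptide`, `protein_id`
#'   (distinct pairs), plus `provenance` and `filtered` attributes.
#' @export
build_peptidome <- function(records, trim = NULL, apply_filter = FALSE,
                            dedup = FALSE, min_len = 6, max_len = 25,
                            excluded_residues = c("M", "C"),
                            il_equivalence = FALSE,
                            provenance = c("target", "background")) {
  provenance <- match.arg(provenance)
  check_records(records)
  if (nrow(records) == 0) abort("`records` must be non-empty")
  if (dedup) records <- dedup_100(records)
  seqs <- records$sequence
  if (!is.null(trim)) seqs <- trim_n_terminus(seqs, trim)
  pep_lists <- lapply(seqs, tryptic_digest)
  if (apply_filter) {
    pep_lists <- lapply(pep_lists, filter_peptides, min_len = min_len,
                        max_len = max_len, excluded_residues = excluded_residues)
  }
  n <- lengths(pep_lists)
  if (sum(n) == 0) {
    abort("Empty peptidome: no peptides remained after trimming/filtering")
  }
  tbl <- tibble::tibble(
    peptide = unlist(pep_lists, use.names = FALSE),
    protein_id = rep(records$protein_id, n)
  )
  if (il_equivalence) tbl$peptide <- chartr("I", "L", tbl$peptide)
  tbl <- dplyr::distinct(tbl) %>% dplyr::arrange(.data$peptide, .data$protein_id)
  new_peptidome(tbl, provenance, filtered = isTRUE(apply_filter))
}

#' @rdname build_peptidome
#' @export
target_peptidome <- function(records, trim = 24, min_len = 6, max_len = 25,
                             excluded_residues = c("M", "C"),
                             il_equivalence = FALSE) {
  build_peptidome(records, trim = trim, apply_filter = TRUE, dedup = TRUE,
                  min_len = min_len, max_len = max_len,
                  excluded_residues = excluded_residues,
                  il_equivalence = il_equivalence, provenance = "target")
}

#' @rdname build_peptidome
#' @export
background_peptidome <- function(records, il_equivalence = FALSE) {
  build_peptidome(records, trim = NULL, apply_filter = FALSE, dedup = FALSE,
                  il_equivalence = il_equivalence, provenance = "background")
}
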