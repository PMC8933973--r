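#' Read a protein FASTA file into a records tibble
#'
#' Reads amino-acid FASTA (for example Prodigal `.faa` output for one MAG)
#' and returns one row per entry. The protein id is the first
#' whitespace-delimited header token; the rest of the header (coordinates,
#' scores) is discarded. Sequences are uppercased and trailing `*` stop
#' characters are stripped.
#'
#' @param path Path to a protein FASTA file.
#' @param mag_id Identifier of the MAG (genome bin) the file belongs to.
#'   Defaults to the file name without extension.
#' @return A tibble with columns `protein_id`, `mag_id`, `sequence`.
#' @examples
#' f <- tempfile(fileext = ".faa")
#' writeLines(c(">p1 hypothetical", "mkaa", ">p2", "GGR"), f)
#' read_fasta(f, mag_id = "mag1")
#' @export
read_fasta <- function(path, mag_id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    return(tibble::tibble(protein_id = character(), mag_id = character(),
                          sequence = character()))
  }
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    abort(paste0("Malformed FASTA: sequence data before first header at line ",
                 first, " of ", path))
  }
  aas <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aas), "\\s+"), `[`, character(1), 1)
  seqs <- toupper(as.character(aas))
  seqs <- gsub("\\s+", "", seqs)
  seqs <- sub("\\*+$", "", seqs)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("Duplicate protein id(s) in ", path, ": ",
                 paste(utils::head(dup, 5), collapse = ", ")))
  }
  if (any(!nzchar(seqs))) {
    abort(paste0("Empty sequence for protein(s): ",
                 paste(utils::head(ids[!nzchar(seqs)], 5), collapse = ", ")))
  }
  tibble::tibble(protein_id = ids, mag_id = mag_id, sequence = unname(seqs))
}

#' Write a records tibble as protein FASTA
#'
#' Inverse of [read_fasta()] on the `(protein_id, sequence)` pairs.
#'
#' @param records Tibble with `protein_id` and `sequence` columns.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path) {
  aas <- Biostrings::AAStringSet(records$sequence)
  names(aas) <- records$protein_id
  Biostrings::writeXStringSet(aas, path, width = 60)
  invisible(path)
}

#' Read a directory of per-MAG FASTA files into one community table
#'
#' Each `.faa`/`.fa`/`.fasta` file is one MAG; the file name (without
#' extension) becomes the `mag_id`.
#'
#' @param dir Directory containing protein FASTA files.
#' @return A tibble with columns `protein_id`, `mag_id`, `sequence`.
#' @export
read_community <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(faa|fa|fasta)$", full.names = TRUE))
  if (length(files) == 0) abort(paste0("No FASTA files found in ", dir))
  recs <- dplyr::bind_rows(lapply(files, read_fasta))
  check_records(recs)
  recs
}

# Strip dbCAN-style decorations from a family cell: coordinate suffixes like
# "GH13_20(25-300)" or "GH13(104)", and split multi-domain "+"-joined labels.
parse_family_cell <- function(cell) {
  if (is.na(cell) || !nzchar(cell) || cell == "-" || cell == "N") return(character())
  labels <- unlist(strsplit(cell, "+", fixed = TRUE))
  labels <- sub("\\(.*\\)$", "", labels)
  labels <- unique(labels[nzchar(labels)])
  bad <- labels[!is_valid_family(labels)]
  if (length(bad) > 0) {
    abort(paste0("Family label(s) not matching the CAZy naming grammar: ",
                 paste(bad, collapse = ", ")))
  }
  labels
}

#' Read a dbCAN2 overview-style annotation table
#'
#' Expects a tab-separated file with a header row naming the protein-id
#' column first and one column per annotation tool (HMMER, DIAMOND, Hotpep;
#' matched case-insensitively). Empty cells and `"-"` both mean "no
#' annotation". Multi-domain cells joined with `+` and coordinate suffixes
#' in parentheses are tolerated and normalised.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `protein_id`, `hmmer`, `diamond`, `hotpep`;
#'   each tool column is a list-column of character vectors of family labels
#'   (possibly empty).
#' @export
read_tool_annotations <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  nm <- tolower(names(df))
  find_col <- function(tool) {
    hit <- which(grepl(tool, nm))
    if (length(hit) == 0) {
      abort(paste0("Annotation table ", path, " lacks a ", toupper(tool), " column"))
    }
    hit[1]
  }
  out <- tibble::tibble(
    protein_id = df[[1]],
    hmmer   = lapply(df[[find_col("hmmer")]], parse_family_cell),
    diamond = lapply(df[[find_col("diamond")]], parse_family_cell),
    hotpep  = lapply(df[[find_col("hotpep")]], parse_family_cell)
  )
  out
}

#' Convert a plain annotation tibble to parsed tool-annotation rows
#'
#' Takes a data frame already in memory (columns `protein_id`, `hmmer`,
#' `diamond`, `hotpep` as strings, `"-"` or empty meaning no annotation)
#' and normalises it to the list-column layout of
#' [read_tool_annotations()].
#'
#' @param df Data frame with the four columns above.
#' @return A tibble with `protein_id` and list-columns `hmmer`, `diamond`,
#'   `hotpep`.
#' @export
as_tool_annotations <- function(df) {
  need <- c("protein_id", "hmmer", "diamond", "hotpep")
  if (!all(need %in% names(df))) {
    abort(paste0("Annotation data must have columns ", paste(need, collapse = ", ")))
  }
  tibble::tibble(
    protein_id = df$protein_id,
    hmmer   = lapply(df$hmmer, parse_family_cell),
    diamond = lapply(df$diamond, parse_family_cell),
    hotpep  = lapply(df$hotpep, parse_family_cell)
  )
}

#' Read a MAG taxonomy table
#'
#' Two tab-separated columns: `mag_id` and `phylum` (the sentinel `"NA"`
#' marks MAGs unassigned at the phylum level).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `mag_id`, `phylum`.
#' @export
read_taxonomy <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, na = character())
  if (!all(c("mag_id", "phylum") %in% names(df))) {
    abort(paste0("Taxonomy table ", path, " must have columns mag_id, phylum"))
  }
  dup <- unique(df$mag_id[duplicated(df$mag_id)])
  if (length(dup) > 0) {
    abort(paste0("Duplicate mag_id(s) in taxonomy: ", paste(dup, collapse = ", ")))
  }
  tibble::as_tibble(df[c("mag_id", "phylum")])
}

#' Read a GhostKOALA-style EC annotation table
#'
#' Tab-separated with columns `protein_id` and `ec`; a cell may carry
#' several comma- or semicolon-separated EC numbers, or `"N/A"` for
#' proteins lacking annotation. Returned in long form, one row per
#' (protein, EC) pair; unannotated proteins are omitted (they map to
#' `"N/A"` downstream).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `protein_id`, `ec`.
#' @export
read_ec_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, na = character())
  if (!all(c("protein_id", "ec") %in% names(df))) {
    abort(paste0("EC table ", path, " must have columns protein_id, ec"))
  }
  out <- tibble::as_tibble(df[c("protein_id", "ec")]) %>%
    dplyr::mutate(ec = strsplit(.data$ec, "[,;]\\s*")) %>%
    tidyr::unnest_longer("ec", keep_empty = FALSE) %>%
    dplyr::filter(nzchar(.data$ec), .data$ec != "N/A", .data$ec != "-")
  bad <- out$ec[!grepl("^[0-9]+\\.[0-9-]+\\.[0-9-]+\\.[0-9-]+$", out$ec)]
  if (length(bad) > 0) {
    abort(paste0("Malformed EC number(s): ", paste(utils::head(bad, 5), collapse = ", ")))
  }
  out
}

#' Write a ranked peptide-selection table
#'
#' Emits the per-family selection as a TSV with one row per selected
#' peptide: `rank`, `peptide`, `n_proteins`, `protein_ids`
#' (semicolon-joined, sorted), `ec_set` and `phylum_set`. Proteins without
#' EC annotation contribute `"N/A"` to `ec_set`; MAGs unassigned at the
#' phylum level contribute `"NA"`.
#'
#' @param result A `peptide_cover` object from [greedy_min_cover()].
#' @param path Output TSV path.
#' @param ec_table Optional long EC table (`protein_id`, `ec`).
#' @param proteins Optional records tibble giving `protein_id` -> `mag_id`.
#' @param taxonomy Optional taxonomy tibble (`mag_id`, `phylum`).
#' @return The path, invisibly.
#' @export
write_selection_table <- function(result, path, ec_table = NULL,
                                  proteins = NULL, taxonomy = NULL) {
  stopifnot(inherits(result, "peptide_cover"))
  if (nrow(result) == 0) abort("Refusing to write an empty selection table")
  ec_of <- function(ids) {
    if (is.null(ec_table)) return("N/A")
    hits <- ec_table$ec[ec_table$protein_id %in% ids]
    labs <- sort(unique(hits))
    n_hit <- length(unique(ec_table$protein_id[ec_table$protein_id %in% ids]))
    if (n_hit < length(ids)) labs <- c(labs, "N/A")
    paste(labs, collapse = ";")
  }
  phy_of <- function(ids) {
    if (is.null(proteins) || is.null(taxonomy)) return("NA")
    mags <- proteins$mag_id[match(ids, proteins$protein_id)]
    phy <- taxonomy$phylum[match(mags, taxonomy$mag_id)]
    phy[is.na(phy)] <- "NA"
    paste(sort(unique(phy)), collapse = ";")
  }
  out <- tibble::tibble(
    rank = result$rank,
    peptide = result$peptide,
    n_proteins = result$n_proteins,
    protein_ids = vapply(result$proteins, function(x) paste(sort(x), collapse = ";"),
                         character(1)),
    ec_set = vapply(result$proteins, ec_of, character(1)),
    phylum_set = vapply(result$proteins, phy_of, character(1))
  )
  readr::write_tsv(out, path, eol = "\n", quote = "none", progress = FALSE)
  invisible(path)
}

#' Re-read a selection table written by [write_selection_table()]
#'
#' Reconstructs the `peptide_cover` object (rank order, peptides, covered
#' protein-id sets); EC/phylum summary columns are carried along as plain
#' columns.
#'
#' @param path Path to the TSV.
#' @param family Family label to attach (optional).
#' @param total_target_proteins Total target-protein count to attach
#'   (defaults to the number of covered proteins).
#' @return A `peptide_cover` tibble.
#' @export
read_selection_table <- function(path, family = NA_character_,
                                 total_target_proteins = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    rank = readr::col_integer(), peptide = readr::col_character(),
    n_proteins = readr::col_integer(), .default = readr::col_character()
  ), progress = FALSE)
  proteins <- strsplit(df$protein_ids, ";", fixed = TRUE)
  covered <- sum(lengths(proteins))
  new_peptide_cover(
    tibble::tibble(rank = df$rank, peptide = df$peptide,
                   n_proteins = df$n_proteins, proteins = proteins),
    family = family,
    total_target_proteins = total_target_proteins %||% covered,
    residual = character()
  )
}
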