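#' Assemble a validated pipeline run configuration
#'
#' Collects every input path and tunable parameter of a run. Defaults are
#' the pipeline's canonical parameters: 24-residue N-terminal trim, 6-25
#' residue peptide window, Met/Cys exclusion, coverage cutoffs at 10, 50,
#' 100 and 200 peptides.
#'
#' @param fasta_dir Directory of per-MAG protein FASTA files.
#' @param annotations Path to the three-tool annotation TSV.
#' @param families Character vector of target family labels (e.g.
#'   `c("GH13", "GH3")`).
#' @param out_dir Output directory.
#' @param taxonomy,ec Optional paths to taxonomy / EC tables.
#' @param assignments Path to the consensus-assignment TSV; defaults to the
#'   one [cmd_annotate()] writes into `out_dir`.
#' @param trim,min_len,max_len,excluded_residues,il_equivalence,cutoffs
#'   Peptide-selection parameters (see [target_peptidome()] and
#'   [coverage_curve()]).
#' @param seed Integer seed (used by [cmd_simulate()]).
#' @return A list of class `run_config`.
#' @export
run_config <- function(fasta_dir = NULL, annotations = NULL,
                       families = character(), out_dir = ".",
                       taxonomy = NULL, ec = NULL,
                       assignments = file.path(out_dir, "assignments.tsv"),
                       trim = 24, min_len = 6, max_len = 25,
                       excluded_residues = c("M", "C"),
                       il_equivalence = FALSE,
                       cutoffs = c(10, 50, 100, 200), seed = 1L) {
  if (length(families) > 0 && any(!is_valid_family(families))) {
    abort(paste0("Invalid target family label(s): ",
                 paste(families[!is_valid_family(families)], collapse = ", ")))
  }
  if (min_len > max_len || min_len < 1) abort("Invalid peptide length bounds")
  if (trim < 0) abort("`trim` must be non-negative")
  structure(list(
    fasta_dir = fasta_dir, annotations = annotations, families = families,
    out_dir = out_dir, taxonomy = taxonomy, ec = ec, assignments = assignments,
    trim = trim, min_len = min_len, max_len = max_len,
    excluded_residues = excluded_residues, il_equivalence = il_equivalence,
    cutoffs = cutoffs, seed = as.integer(seed)
  ), class = "run_config")
}

#' Annotate: consensus families and CAZyme census
#'
#' Reads the three-tool annotation table and the community FASTA
#' directory, applies the consensus rule, and writes `assignments.tsv`
#' (protein_id, family, evidence), `census_per_mag.tsv` and — when a
#' taxonomy table is configured — `census_per_phylum.tsv` into the output
#' directory. Without taxonomy the per-phylum rollup is skipped with a
#' warning.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `assignments` and `census`.
#' @export
cmd_annotate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- read_tool_annotations(config$annotations)
  assignments <- consensus_families(rows)
  proteins <- read_community(config$fasta_dir)
  taxonomy <- if (!is.null(config$taxonomy)) read_taxonomy(config$taxonomy) else NULL
  if (is.null(taxonomy)) warn("No taxonomy table: per-phylum census rollup skipped")
  census <- cazyme_census(assignments, proteins, taxonomy)
  inform(paste0("annotate: ", nrow(proteins), " proteins in, ",
                length(unique(assignments$protein_id)), " consensus CAZymes"))
  readr::write_tsv(assignments, config$assignments, eol = "\n", quote = "none",
                   progress = FALSE)
  readr::write_tsv(census$per_mag, file.path(config$out_dir, "census_per_mag.tsv"),
                   eol = "\n", quote = "none", progress = FALSE)
  if (!is.null(census$per_phylum)) {
    readr::write_tsv(census$per_phylum,
                     file.path(config$out_dir, "census_per_phylum.tsv"),
                     eol = "\n", quote = "none", progress = FALSE)
  }
  invisible(list(assignments = assignments, census = census))
}

#' Select: family-unique peptides and greedy minimum covers
#'
#' For every configured target family: partitions the community into
#' targets and background, builds the filtered target peptidome
#' (deduplicated, trimmed) and the raw background peptidome, keeps
#' family-unique peptides, runs the greedy cover, and writes per-family
#' outputs: `selection_<family>.tsv` (ranked table with EC/phylum sets),
#' `coverage_<family>.tsv`, `residual_<family>.txt` (uncovered seed ids).
#' A `run_manifest.json` records parameters, input checksums and stage
#' counts. Families whose unique-peptide set is empty still get a residual
#' list and are flagged in the returned status.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `covers` (named list of `peptide_cover`),
#'   `status` (`"ok"` or `"empty-result"`), and `manifest`.
#' @export
cmd_select <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (length(config$families) == 0) abort("No target families configured")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  proteins <- read_community(config$fasta_dir)
  assignments <- readr::read_tsv(config$assignments,
                                 col_types = readr::cols(.default = readr::col_character()),
                                 progress = FALSE)
  taxonomy <- if (!is.null(config$taxonomy)) read_taxonomy(config$taxonomy) else NULL
  ec_table <- if (!is.null(config$ec)) read_ec_table(config$ec) else NULL

  covers <- list()
  fam_stats <- list()
  any_empty <- FALSE
  for (fam in config$families) {
    parts <- split_target_background(proteins, assignments, fam)
    seeds <- dedup_100(parts$targets)
    target_pd <- tryCatch(
      target_peptidome(seeds, trim = config$trim, min_len = config$min_len,
                       max_len = config$max_len,
                       excluded_residues = config$excluded_residues,
                       il_equivalence = config$il_equivalence),
      error = function(e) NULL
    )
    background_pd <- background_peptidome(parts$background,
                                          il_equivalence = config$il_equivalence)
    unique_pd <- if (is.null(target_pd)) NULL else {
      unique_target_peptides(target_pd, background_pd)
    }
    n_unique <- if (is.null(unique_pd)) 0L else length(unique(unique_pd$peptide))
    if (n_unique == 0) {
      any_empty <- TRUE
      writeLines(sort(seeds$protein_id),
                 file.path(config$out_dir, paste0("residual_", fam, ".txt")))
      inform(paste0("select ", fam, ": ", nrow(parts$targets), " targets, ",
                    nrow(seeds), " seeds, 0 unique peptides (empty result)"))
      fam_stats[[fam]] <- list(targets = nrow(parts$targets), seeds = nrow(seeds),
                               unique_peptides = 0L, selected = 0L)
      next
    }
    cover <- greedy_min_cover(unique_pd, family = fam,
                              total_target_proteins = nrow(seeds),
                              all_protein_ids = seeds$protein_id)
    covers[[fam]] <- cover
    write_selection_table(cover,
                          file.path(config$out_dir, paste0("selection_", fam, ".tsv")),
                          ec_table = ec_table, proteins = proteins,
                          taxonomy = taxonomy)
    readr::write_tsv(coverage_curve(cover, config$cutoffs),
                     file.path(config$out_dir, paste0("coverage_", fam, ".tsv")),
                     eol = "\n", quote = "none", progress = FALSE)
    writeLines(attr(cover, "residual"),
               file.path(config$out_dir, paste0("residual_", fam, ".txt")))
    inform(paste0("select ", fam, ": ", nrow(parts$targets), " targets, ",
                  nrow(seeds), " seeds, ",
                  length(unique(target_pd$peptide)), " filtered peptides, ",
                  n_unique, " unique, ", nrow(cover), " selected groups"))
    fam_stats[[fam]] <- list(
      targets = nrow(parts$targets), seeds = nrow(seeds),
      filtered_peptides = length(unique(target_pd$peptide)),
      unique_peptides = n_unique, selected = nrow(cover),
      proteins_covered = sum(cover$n_proteins)
    )
  }
  inputs <- c(config$annotations, config$assignments, config$taxonomy, config$ec)
  inputs <- inputs[file.exists(inputs)]
  checksums <- stats::setNames(as.list(unname(tools::md5sum(inputs))),
                               basename(inputs))
  manifest <- list(
    parameters = config[c("families", "trim", "min_len", "max_len",
                          "excluded_residues", "il_equivalence", "cutoffs")],
    inputs = checksums,
    families = fam_stats
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(covers = covers,
                 status = if (any_empty) "empty-result" else "ok",
                 manifest = manifest))
}

#' Simulate: write a synthetic community in pipeline input layout
#'
#' Thin wrapper over [simulate_community()] + [write_community()] wired to
#' a [run_config()]'s seed and output directory.
#'
#' @param config A [run_config()]; `out_dir` and `seed` are used.
#' @param spec Optional [community_spec()]; its seed is overridden by the
#'   config seed.
#' @return Invisibly, the simulated `mag_community`.
#' @export
cmd_simulate <- function(config, spec = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(spec)) spec <- community_spec(seed = config$seed)
  else spec$seed <- config$seed
  sim <- simulate_community(spec)
  write_community(sim, config$out_dir)
  inform(paste0("simulate: ", nrow(sim$proteins), " proteins in ",
                spec$n_mags, " MAGs written to ", config$out_dir))
  invisible(sim)
}

#' Run the full selection pipeline on an in-memory community
#'
#' Convenience composition used by tests and examples: consensus
#' annotation, per-family target/background split, peptidome construction,
#' uniqueness comparison and greedy cover — all without touching disk.
#'
#' @param proteins Records tibble.
#' @param annotations Plain annotation tibble (see [as_tool_annotations()]).
#' @param families Target family labels.
#' @param ... Passed to [target_peptidome()].
#' @return A list with `assignments`, and per-family lists `unique_peps`
#'   and `covers`.
#' @export
select_family_peptides <- function(proteins, annotations, families, ...) {
  asg <- consensus_families(as_tool_annotations(annotations))
  unique_peps <- list()
  covers <- list()
  for (fam in families) {
    parts <- split_target_background(proteins, asg, fam)
    seeds <- dedup_100(parts$targets)
    tp <- target_peptidome(seeds, ...)
    bp <- background_peptidome(parts$background)
    up <- unique_target_peptides(tp, bp)
    unique_peps[[fam]] <- up
    if (nrow(up) > 0) {
      covers[[fam]] <- greedy_min_cover(up, family = fam,
                                        total_target_proteins = nrow(seeds),
                                        all_protein_ids = seeds$protein_id)
    }
  }
  list(assignments = asg, unique_peps = unique_peps, covers = covers)
}
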