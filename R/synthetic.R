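# Background residue frequencies approximating natural protein composition;
# K+R ~ 11% gives a mean tryptic peptide length of ~9 residues.
DEFAULT_RESIDUE_FREQS <- c(
  A = 0.083, C = 0.014, D = 0.055, E = 0.068, F = 0.039, G = 0.071,
  H = 0.023, I = 0.060, K = 0.058, L = 0.097, M = 0.024, N = 0.040,
  P = 0.047, Q = 0.039, R = 0.055, S = 0.066, T = 0.053, V = 0.069,
  W = 0.011, Y = 0.029
)

#' Specify a synthetic MAG community
#'
#' Parameterises a mock community of MAG proteomes in which each CAZyme
#' family's members share planted conserved sequence blocks (hence shared
#' tryptic peptides) against a random background — the structure the
#' peptide-selection pipeline exploits in real communities. Defaults
#' describe a 50-MAG community with three GH families of 20 members each,
#' one planted block per family.
#'
#' @param n_mags Number of MAGs.
#' @param phyla Named numeric vector of phylum proportions (sums to 1).
#' @param families Tibble with one row per planted family: `family` label,
#'   `n_member_mags` (MAGs carrying the family), `members_per_mag`,
#'   `n_blocks` (planted conserved blocks shared by all members), `ec`
#'   (EC number annotated on members).
#' @param background_per_mag Integer range (lo, hi) of non-family proteins
#'   per MAG.
#' @param protein_length Integer range of protein lengths (residues); the
#'   minimum must exceed the 24-residue N-terminal trim so planted blocks
#'   can be inserted beyond it.
#' @param residue_freqs Named distribution over the 20 canonical residues
#'   for random sequence; the K+R mass controls tryptic peptide length.
#' @param block_peptide_length Integer range of planted-peptide lengths
#'   (kept within the 6-25 filter window).
#' @param decoy_rate Probability that a planted block is also inserted into
#'   a random background protein, destroying that peptide's uniqueness.
#' @param single_tool_rate Fraction of family members annotated by a single
#'   tool only, which the consensus rule discards (those members then fall
#'   into the background and mask their own planted peptides — useful to
#'   exercise the discard rule, so the default is 0).
#' @param other_cazyme_rate Fraction of background proteins given a
#'   non-target CAZyme annotation (GT/CE/CBM), for census realism.
#' @param seed Integer RNG seed; the whole community is reproducible from it.
#' @return A validated list of class `community_spec`.
#' @export
community_spec <- function(n_mags = 50,
                           phyla = c(Firmicutes = 0.5, Bacteroidota = 0.3,
                                     Proteobacteria = 0.2),
                           families = tibble::tibble(
                             family = c("GH13", "GH3", "GH2"),
                             n_member_mags = 20,
                             members_per_mag = 1,
                             n_blocks = 1,
                             ec = c("3.2.1.1", "3.2.1.21", "3.2.1.23")
                           ),
                           background_per_mag = c(20, 40),
                           protein_length = c(120, 400),
                           residue_freqs = DEFAULT_RESIDUE_FREQS,
                           block_peptide_length = c(9, 14),
                           decoy_rate = 0,
                           single_tool_rate = 0,
                           other_cazyme_rate = 0.05,
                           seed = 1L) {
  fail <- function(field, why) abort(paste0("Invalid community spec: `", field, "` ", why))
  if (n_mags < 1) fail("n_mags", "must be positive")
  if (abs(sum(phyla) - 1) > 1e-6) fail("phyla", "proportions must sum to 1")
  if (is.null(names(phyla)) || any(!nzchar(names(phyla)))) fail("phyla", "must be named")
  need <- c("family", "n_member_mags", "members_per_mag", "n_blocks", "ec")
  if (!all(need %in% names(families))) {
    fail("families", paste0("must have columns ", paste(need, collapse = ", ")))
  }
  if (any(!is_valid_family(families$family))) fail("families", "has invalid family labels")
  if (any(families$n_member_mags > n_mags)) fail("families$n_member_mags", "exceeds n_mags")
  if (any(families$n_member_mags < 1) || any(families$members_per_mag < 1) ||
      any(families$n_blocks < 1)) {
    fail("families", "counts must be positive")
  }
  if (length(background_per_mag) != 2 || background_per_mag[1] < 1 ||
      background_per_mag[2] < background_per_mag[1]) {
    fail("background_per_mag", "must be an increasing positive range")
  }
  if (length(protein_length) != 2 || protein_length[2] < protein_length[1]) {
    fail("protein_length", "must be an increasing range")
  }
  if (protein_length[1] <= 24 + 2) {
    fail("protein_length", "minimum must exceed the 24-residue trim (block would not fit)")
  }
  if (!setequal(names(residue_freqs), AA20)) fail("residue_freqs", "must cover the 20 residues")
  if (block_peptide_length[1] < 6 || block_peptide_length[2] > 25 ||
      block_peptide_length[2] < block_peptide_length[1]) {
    fail("block_peptide_length", "must lie within the 6-25 filter window")
  }
  if (block_peptide_length[2] + 2 > protein_length[1]) {
    fail("block_peptide_length", "block longer than the shortest protein")
  }
  if (decoy_rate < 0 || decoy_rate > 1) fail("decoy_rate", "must be in [0, 1]")
  if (single_tool_rate < 0 || single_tool_rate > 1) fail("single_tool_rate", "must be in [0, 1]")
  structure(list(
    n_mags = as.integer(n_mags), phyla = phyla / sum(phyla), families = families,
    background_per_mag = as.integer(background_per_mag),
    protein_length = as.integer(protein_length),
    residue_freqs = residue_freqs / sum(residue_freqs),
    block_peptide_length = as.integer(block_peptide_length),
    decoy_rate = decoy_rate, single_tool_rate = single_tool_rate,
    other_cazyme_rate = other_cazyme_rate, seed = as.integer(seed)
  ), class = "community_spec")
}

random_sequence <- function(len, freqs) {
  paste(sample(names(freqs), len, replace = TRUE, prob = freqs), collapse = "")
}

# A planted block is K/R + peptide + G: the flanks guarantee the peptide is
# emitted intact by tryptic digestion wherever the block lands, and the
# peptide body avoids K/R/M/C/P so it survives the empirical filters.
random_planted_block <- function(len_range) {
  body_pool <- setdiff(AA20, c("K", "R", "M", "C", "P"))
  len <- sample(seq(len_range[1], len_range[2]), 1)
  body <- paste(sample(body_pool, len - 1, replace = TRUE), collapse = "")
  pep <- paste0(body, sample(c("K", "R"), 1))
  list(peptide = pep, block = paste0(sample(c("K", "R"), 1), pep, "G"))
}

insert_block <- function(seq, block, min_pos = 24) {
  len <- nchar(seq)
  pos <- sample(seq(min_pos, len), 1)
  paste0(substr(seq, 1, pos), block, substr(seq, pos + 1, len))
}

#' Simulate a synthetic MAG community with planted family peptides
#'
#' Generates per-MAG proteomes, a three-tool annotation table, taxonomy and
#' EC tables, and a truth manifest recording every planted peptide, its
#' intended family members and any decoy placements. Family members carry
#' the family's conserved blocks inserted after position 24, so the
#' N-terminal trim cannot delete them. Reproducible: the same spec (and
#' seed) yields byte-identical outputs.
#'
#' @param spec A [community_spec()].
#' @return A list of class `mag_community`: `proteins` (records tibble),
#'   `annotations` (plain string tibble in dbCAN2 overview layout),
#'   `taxonomy`, `ec` (long tibble), `manifest` (list with `planted` and
#'   `decoys` tibbles), and `spec`.
#' @export
simulate_community <- function(spec = community_spec()) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(spec$seed)
  mags <- sprintf("mag%03d", seq_len(spec$n_mags))
  taxonomy <- tibble::tibble(
    mag_id = mags,
    phylum = sample(names(spec$phyla), spec$n_mags, replace = TRUE,
                    prob = spec$phyla)
  )

  rand_len <- function() sample(seq(spec$protein_length[1], spec$protein_length[2]), 1)

  # Family members with planted blocks.
  member_rows <- list()
  planted_rows <- list()
  fam_blocks <- list()
  for (i in seq_len(nrow(spec$families))) {
    fam <- spec$families$family[i]
    blocks <- lapply(seq_len(spec$families$n_blocks[i]), function(j) {
      random_planted_block(spec$block_peptide_length)
    })
    fam_blocks[[fam]] <- blocks
    member_mags <- sort(sample(mags, spec$families$n_member_mags[i]))
    for (m in member_mags) {
      for (k in seq_len(spec$families$members_per_mag[i])) {
        pid <- paste(m, fam, k, sep = "_")
        seq <- random_sequence(rand_len(), spec$residue_freqs)
        for (b in blocks) seq <- insert_block(seq, b$block)
        member_rows[[length(member_rows) + 1]] <-
          tibble::tibble(protein_id = pid, mag_id = m, sequence = seq, family = fam)
        for (b in blocks) {
          planted_rows[[length(planted_rows) + 1]] <-
            tibble::tibble(family = fam, peptide = b$peptide, protein_id = pid)
        }
      }
    }
  }
  members <- dplyr::bind_rows(member_rows)

  # Background proteins.
  bg_rows <- lapply(mags, function(m) {
    nb <- sample(seq(spec$background_per_mag[1], spec$background_per_mag[2]), 1)
    tibble::tibble(
      protein_id = paste0(m, "_b", seq_len(nb)),
      mag_id = m,
      sequence = vapply(seq_len(nb), function(i) {
        random_sequence(rand_len(), spec$residue_freqs)
      }, character(1))
    )
  })
  background <- dplyr::bind_rows(bg_rows)

  # Decoy placements: planted blocks re-inserted into background proteins.
  decoys <- tibble::tibble(peptide = character(), protein_id = character())
  for (fam in names(fam_blocks)) {
    for (b in fam_blocks[[fam]]) {
      if (stats::runif(1) < spec$decoy_rate) {
        victim <- sample(background$protein_id, 1)
        j <- match(victim, background$protein_id)
        background$sequence[j] <- insert_block(background$sequence[j], b$block,
                                               min_pos = 1)
        decoys <- dplyr::bind_rows(decoys,
                                   tibble::tibble(peptide = b$peptide, protein_id = victim))
      }
    }
  }

  proteins <- dplyr::bind_rows(
    members[c("protein_id", "mag_id", "sequence")], background
  ) %>% dplyr::arrange(.data$mag_id, .data$protein_id)

  # Annotation table: members by >= 2 tools (or 1, to exercise the discard
  # rule); a slice of background proteins gets non-target CAZyme labels.
  ann_members <- members %>%
    dplyr::mutate(
      pattern = ifelse(stats::runif(dplyr::n()) < spec$single_tool_rate,
                       "single",
                       sample(c("hmmer_diamond", "diamond_hotpep"),
                              dplyr::n(), replace = TRUE, prob = c(0.6, 0.4))),
      hmmer = ifelse(.data$pattern %in% c("hmmer_diamond", "single"), .data$family, "-"),
      diamond = ifelse(.data$pattern %in% c("hmmer_diamond", "diamond_hotpep"),
                       .data$family, "-"),
      hotpep = ifelse(.data$pattern == "diamond_hotpep", .data$family, "-")
    ) %>%
    dplyr::select("protein_id", "hmmer", "diamond", "hotpep")
  other_fams <- c("GT2", "CE1", "CBM50", "GT4", "AA3")
  n_other <- round(spec$other_cazyme_rate * nrow(background))
  other_ids <- if (n_other > 0) sample(background$protein_id, n_other) else character()
  ann_other <- tibble::tibble(
    protein_id = other_ids,
    hmmer = sample(other_fams, length(other_ids), replace = TRUE),
    diamond = NA_character_, hotpep = "-"
  ) %>% dplyr::mutate(diamond = .data$hmmer)
  ann_empty <- tibble::tibble(
    protein_id = setdiff(background$protein_id, other_ids),
    hmmer = "-", diamond = "-", hotpep = "-"
  )
  annotations <- dplyr::bind_rows(ann_members, ann_other, ann_empty) %>%
    dplyr::arrange(.data$protein_id)

  ec <- members %>%
    dplyr::left_join(spec$families[c("family", "ec")], by = "family") %>%
    dplyr::select("protein_id", "ec") %>%
    dplyr::arrange(.data$protein_id)

  planted <- dplyr::bind_rows(planted_rows) %>%
    dplyr::arrange(.data$family, .data$peptide, .data$protein_id)

  structure(list(
    proteins = proteins, annotations = annotations, taxonomy = taxonomy,
    ec = ec, manifest = list(planted = planted, decoys = decoys),
    spec = spec
  ), class = "mag_community")
}

#' @export
print.mag_community <- function(x, ...) {
  cat("<mag_community>", nrow(x$proteins), "proteins in", x$spec$n_mags, "MAGs;",
      nrow(x$spec$families), "planted families;",
      nrow(x$manifest$decoys), "decoy placements\n")
  invisible(x)
}

#' Write a simulated community to disk in pipeline input formats
#'
#' Emits exactly the files the readers consume: per-MAG protein FASTA under
#' `dir/fasta/`, `annotations.tsv`, `taxonomy.tsv`, `ec.tsv`, and
#' `truth_manifest.tsv` (planted and decoy placements).
#'
#' @param sim A `mag_community` from [simulate_community()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_community <- function(sim, dir) {
  stopifnot(inherits(sim, "mag_community"))
  fdir <- file.path(dir, "fasta")
  dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
  for (m in unique(sim$proteins$mag_id)) {
    write_fasta(sim$proteins[sim$proteins$mag_id == m, ],
                file.path(fdir, paste0(m, ".faa")))
  }
  readr::write_tsv(sim$annotations, file.path(dir, "annotations.tsv"),
                   eol = "\n", quote = "none", progress = FALSE)
  readr::write_tsv(sim$taxonomy, file.path(dir, "taxonomy.tsv"),
                   eol = "\n", quote = "none", progress = FALSE)
  readr::write_tsv(sim$ec, file.path(dir, "ec.tsv"),
                   eol = "\n", quote = "none", progress = FALSE)
  manifest <- dplyr::bind_rows(
    dplyr::mutate(sim$manifest$planted, role = "planted"),
    dplyr::mutate(sim$manifest$decoys, family = NA_character_, role = "decoy")
  )
  readr::write_tsv(manifest[c("role", "family", "peptide", "protein_id")],
                   file.path(dir, "truth_manifest.tsv"),
                   eol = "\n", quote = "none", progress = FALSE)
  invisible(dir)
}

#' Score selected peptides against the planted truth
#'
#' For each planted family, compares the greedy selection against the truth
#' manifest: recall is the fraction of planted-and-unique peptides that
#' were selected (planted peptides destroyed by decoys are not expected to
#' be recoverable), precision the fraction of selected peptides that were
#' planted, and member coverage the fraction of intended member proteins
#' appearing in the covered sets.
#'
#' @param manifest The `manifest` element of a `mag_community` (list with
#'   `planted` and `decoys` tibbles).
#' @param covers Named list of `peptide_cover` objects, one per family (or
#'   a single `peptide_cover` whose `family` attribute matches a planted
#'   family).
#' @param unique_peps Optional named list of family-unique `peptidome`s,
#'   used to restrict the recall denominator to planted peptides that
#'   survived the uniqueness comparison.
#' @return A tibble with one row per family: `family`, `n_planted`,
#'   `n_planted_unique`, `n_planted_selected`, `recall`, `precision`,
#'   `n_members`, `n_members_covered`, `uncovered_members` (list-column).
#' @export
verify_recovery <- function(manifest, covers, unique_peps = NULL) {
  if (inherits(covers, "peptide_cover")) {
    covers <- stats::setNames(list(covers), attr(covers, "family"))
  }
  rows <- lapply(names(covers), function(fam) {
    cov <- covers[[fam]]
    pl <- manifest$planted[manifest$planted$family == fam, ]
    planted_peps <- unique(pl$peptide)
    members <- unique(pl$protein_id)
    covered <- unlist(cov$proteins, use.names = FALSE)
    planted_unique <- if (!is.null(unique_peps) && !is.null(unique_peps[[fam]])) {
      intersect(planted_peps, unique_peps[[fam]]$peptide)
    } else {
      setdiff(planted_peps, manifest$decoys$peptide)
    }
    selected_planted <- intersect(cov$peptide, planted_peps)
    tibble::tibble(
      family = fam,
      n_planted = length(planted_peps),
      n_planted_unique = length(planted_unique),
      n_planted_selected = length(intersect(selected_planted, planted_unique)),
      recall = if (length(planted_unique) > 0) {
        length(intersect(selected_planted, planted_unique)) / length(planted_unique)
      } else NA_real_,
      precision = if (nrow(cov) > 0) length(selected_planted) / nrow(cov) else NA_real_,
      n_members = length(members),
      n_members_covered = length(intersect(members, covered)),
      uncovered_members = list(setdiff(members, covered))
    )
  })
  dplyr::bind_rows(rows)
}
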