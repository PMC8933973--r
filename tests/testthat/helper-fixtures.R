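# Shared fixtures and independent oracles for the test suite.

# The worked six-peptide / seven-protein example: peptide 1 is shared by the
# majority of proteins; peptide 4's proteins are all absorbed by peptide 1;
# peptides 3 and 6 tie on protein B.
fig_s1_sets <- function() {
  list(
    PEP1 = c("A", "D", "E", "F"),
    PEP2 = c("A", "D"),
    PEP3 = c("B", "E"),
    PEP4 = c("D", "F"),
    PEP5 = c("C", "G"),
    PEP6 = c("B")
  )
}

sets_to_peptidome <- function(sets, provenance = "target", filtered = TRUE) {
  df <- tibble::tibble(
    peptide = rep(names(sets), lengths(sets)),
    protein_id = unlist(sets, use.names = FALSE)
  )
  as_peptidome(df, provenance = provenance, filtered = filtered)
}

fig_s1_peptidome <- function() sets_to_peptidome(fig_s1_sets())

# Independent tryptic-digestion oracle: perl regex split at K/R not followed
# by P (deliberately a different route from the package's position scan).
regex_digest_oracle <- function(seq) {
  if (!nzchar(seq)) return(character(0))
  strsplit(seq, "(?<=[KR])(?!P)", perl = TRUE)[[1]]
}

random_aa_sequence <- function(len, alphabet = c("A", "G", "K", "R", "P", "L",
                                                 "S", "T", "V", "E")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Random small set-cover instance as a peptidome.
random_cover_instance <- function(max_pep = 12, max_prot = 15) {
  n_pep <- sample(2:max_pep, 1)
  n_prot <- sample(2:max_prot, 1)
  prots <- paste0("prot", seq_len(n_prot))
  sets <- lapply(seq_len(n_pep), function(i) {
    sample(prots, sample(seq_len(n_prot), 1))
  })
  names(sets) <- sprintf("PEPTIDE%02d", seq_len(n_pep))
  sets_to_peptidome(sets)
}

# Per-step greedy oracle: replays the selection against independently
# maintained sets and checks every pick has maximal current cardinality.
check_greedy_steps <- function(sets, cover) {
  remaining <- lapply(sets, unique)
  for (i in seq_len(nrow(cover))) {
    sizes <- lengths(remaining)
    if (length(sizes) == 0) return(FALSE)
    if (cover$n_proteins[i] != max(sizes)) return(FALSE)
    pick <- cover$peptide[i]
    if (!pick %in% names(remaining)) return(FALSE)
    if (!setequal(remaining[[pick]], cover$proteins[[i]])) return(FALSE)
    covered <- remaining[[pick]]
    remaining[[pick]] <- NULL
    remaining <- lapply(remaining, setdiff, y = covered)
    remaining <- remaining[lengths(remaining) > 0]
  }
  length(remaining) == 0
}

# Small in-memory community for IO/pipeline tests.
tiny_community <- function(seed = 42) {
  simulate_community(community_spec(
    n_mags = 6,
    phyla = c(Firmicutes = 0.5, Bacteroidota = 0.5),
    families = tibble::tibble(family = c("GH13", "GH3"), n_member_mags = 4,
                              members_per_mag = 1, n_blocks = 1,
                              ec = c("3.2.1.1", "3.2.1.21")),
    background_per_mag = c(4, 8),
    protein_length = c(80, 150),
    seed = seed
  ))
}
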