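test_that("unique peptides are the target peptides absent from the background", {
  tgt <- as_peptidome(tibble::tibble(peptide = c("PEPTIDER", "OTHERK"),
                                     protein_id = c("p1", "p2")),
                      "target", filtered = TRUE)
  bg <- as_peptidome(tibble::tibble(peptide = "PEPTIDER", protein_id = "b1"),
                     "background")
  u <- unique_target_peptides(tgt, bg)
  expect_equal(u$peptide, "OTHERK")

  bg2 <- as_peptidome(tibble::tibble(peptide = "UNRELATEDK", protein_id = "b1"),
                      "background")
  u2 <- unique_target_peptides(tgt, bg2)
  expect_equal(u2$peptide, tgt$peptide)

  bg3 <- as_peptidome(tibble::tibble(peptide = c("PEPTIDER", "OTHERK"),
                                     protein_id = "b1"), "background")
  expect_message(u3 <- unique_target_peptides(tgt, bg3), "No family-unique")
  expect_equal(nrow(u3), 0)
})

test_that("greedy cover reproduces the worked six-peptide example", {
  cover <- greedy_min_cover(fig_s1_peptidome(), family = "GH13")
  expect_equal(cover$peptide[1], "PEP1")
  expect_setequal(cover$proteins[[1]], c("A", "D", "E", "F"))
  expect_equal(cover$peptide[2], "PEP5")
  expect_setequal(cover$proteins[[2]], c("C", "G"))
  # PEP3 and PEP6 tie on protein B; lexicographic tie-break picks PEP3
  expect_equal(cover$peptide[3], "PEP3")
  expect_equal(cover$proteins[[3]], "B")
  expect_equal(cover$n_proteins, c(4, 2, 1))
  expect_setequal(unlist(cover$proteins), LETTERS[1:7])
})

test_that("a single peptide covering everything yields a one-row cover", {
  pd <- sets_to_peptidome(list(ALLPEPK = c("a", "b", "c"), SMALLK = "a"))
  cover <- greedy_min_cover(pd)
  expect_equal(nrow(cover), 1)
  expect_equal(cover$peptide, "ALLPEPK")
})

test_that("greedy cover is independent of input row order", {
  pd <- fig_s1_peptidome()
  shuffled <- as_peptidome(pd[sample(nrow(pd)), ], "target", filtered = TRUE)
  a <- greedy_min_cover(pd)
  b <- greedy_min_cover(shuffled)
  expect_equal(tidy(a), tidy(b))
})

test_that("greedy invariants hold on random instances (disjoint, monotone, per-step max)", {
  set.seed(303)
  for (i in 1:50) {
    pd <- random_cover_instance()
    cover <- greedy_min_cover(pd)
    # disjoint covered sets
    all_covered <- unlist(cover$proteins)
    expect_equal(length(all_covered), length(unique(all_covered)))
    # monotone non-increasing group sizes
    expect_true(all(diff(cover$n_proteins) <= 0))
    # complete: every protein with >= 1 peptide is covered exactly once
    expect_setequal(all_covered, unique(pd$protein_id))
    # each step picks a set of maximal current cardinality
    sets <- split(pd$protein_id, pd$peptide)
    expect_true(check_greedy_steps(sets, cover))
  }
})

test_that("exhaustive minimum cover bounds the greedy from below", {
  expect_equal(brute_force_min_cover(fig_s1_peptidome()), 3L)
  # one peptide per protein forces n picks
  pd <- sets_to_peptidome(list(AK = "p1", BK = "p2", CK = "p3"))
  expect_equal(brute_force_min_cover(pd), 3L)
  set.seed(404)
  for (i in 1:30) {
    pd <- random_cover_instance(max_pep = 8, max_prot = 10)
    expect_gte(nrow(greedy_min_cover(pd)), brute_force_min_cover(pd))
  }
})

test_that("brute force refuses oversized instances", {
  pd <- sets_to_peptidome(stats::setNames(
    as.list(paste0("p", 1:20)), sprintf("PEPTIDE%02d", 1:20)))
  expect_error(brute_force_min_cover(pd, max_peptides = 15), "too large")
})

test_that("coverage curve percentages follow the ranked prefix sums", {
  cover <- greedy_min_cover(fig_s1_peptidome(), total_target_proteins = 7)
  cc <- coverage_curve(cover, cutoffs = c(1, 2, 3, 10))
  expect_equal(cc$percent_covered, c(4, 6, 7, 7) / 7 * 100)
  expect_equal(round(cc$percent_covered[1], 2), 57.14)
  expect_true(all(diff(cc$percent_covered) >= 0))
  expect_true(all(cc$percent_covered <= 100))
  expect_error(coverage_curve(cover, cutoffs = c(0, 10)), "positive")
})

test_that("coverage accounts for target proteins with no unique peptide", {
  cover <- greedy_min_cover(fig_s1_peptidome(), total_target_proteins = 10,
                            all_protein_ids = c(LETTERS[1:7], "H", "I", "J"))
  expect_setequal(attr(cover, "residual"), c("H", "I", "J"))
  cc <- coverage_curve(cover, cutoffs = 100)
  expect_equal(cc$percent_covered, 70)
})

test_that("EC grouping keys are the distinct EC sets of covered proteins", {
  cover <- greedy_min_cover(fig_s1_peptidome())
  ec <- tibble::tibble(
    protein_id = c("A", "D", "E", "F", "C", "G"),
    ec = c("3.2.1.23", "3.2.1.23", "3.2.1.23", "3.2.1.23",
           "3.2.1.54", "3.2.1.135")
  )
  g <- group_by_ec(cover, ec)
  expect_true("3.2.1.23" %in% g$ec_set)
  expect_true("3.2.1.135;3.2.1.54" %in% g$ec_set)   # composite key, sorted
  expect_true("N/A" %in% g$ec_set)                   # protein B unannotated
  expect_equal(sum(g$n_proteins), 7)
  expect_equal(sum(g$n_peptides), 3)
  # without an EC table everything is N/A
  g0 <- group_by_ec(cover, NULL)
  expect_equal(g0$ec_set, "N/A")
})

fig_s1_proteins <- function() {
  tibble::tibble(protein_id = LETTERS[1:7],
                 mag_id = c("m1", "m1", "m2", "m1", "m1", "m1", "m2"),
                 sequence = "AAAA")
}

test_that("phylum grouping counts covered proteins per phylum and flags specificity", {
  cover <- greedy_min_cover(fig_s1_peptidome())
  tax <- tibble::tibble(mag_id = c("m1", "m2"), phylum = c("Firmicutes", "Bacteroidota"))
  g <- group_by_phylum(cover, fig_s1_proteins(), tax)
  p1 <- g[g$peptide == "PEP1", ]
  expect_equal(p1$phylum, "Firmicutes")
  expect_equal(p1$n_proteins, 4)
  expect_true(p1$taxon_specific)
  p5 <- g[g$peptide == "PEP5", ]   # C (m2) + G (m2) -> Bacteroidota only
  expect_equal(p5$phylum, "Bacteroidota")
  # unannotated MAG falls in the NA bucket and is not taxon-specific
  tax2 <- tibble::tibble(mag_id = "m1", phylum = "Firmicutes")
  g2 <- group_by_phylum(cover, fig_s1_proteins(), tax2)
  expect_true("NA" %in% g2$phylum)
  expect_false(any(g2$taxon_specific[g2$phylum == "NA"]))
})

test_that("peptides needed to cover a phylum use the ranked-prefix convention", {
  cover <- greedy_min_cover(fig_s1_peptidome())
  tax <- tibble::tibble(mag_id = c("m1", "m2"), phylum = c("Firmicutes", "Bacteroidota"))
  prot <- fig_s1_proteins()
  # Firmicutes proteins A,B,D,E,F sit in groups 1 and 3 -> prefix 3
  expect_equal(peptides_to_cover_taxon(cover, prot, tax, "Firmicutes"), 3L)
  # Bacteroidota proteins C,G are all in group 2 -> prefix 2
  expect_equal(peptides_to_cover_taxon(cover, prot, tax, "Bacteroidota"), 2L)
  expect_equal(peptides_to_cover_taxon(cover, prot, tax, "Chloroflexi"), 0L)
  # restricted mode re-runs greedy on the phylum's proteins only
  expect_equal(
    peptides_to_cover_taxon(cover, prot, tax, "Bacteroidota",
                            mode = "restricted", unique_pep = fig_s1_peptidome()),
    1L)
})

test_that("tidy and glance summarise a cover", {
  cover <- greedy_min_cover(fig_s1_peptidome(), family = "GH13",
                            total_target_proteins = 7)
  td <- tidy(cover)
  expect_equal(td$protein_ids[1], "A;D;E;F")
  gl <- glance(cover)
  expect_equal(gl$n_peptides, 3)
  expect_equal(gl$pct_covered, 100)
  expect_equal(gl$max_proteins_per_peptide, 4)
})
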