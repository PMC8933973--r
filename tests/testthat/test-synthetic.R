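test_that("community_spec validates its fields by name", {
  expect_error(community_spec(phyla = c(A = 0.5, B = 0.3)), "phyla")
  expect_error(community_spec(protein_length = c(10, 50)), "protein_length")
  expect_error(community_spec(n_mags = 5,
                              families = tibble::tibble(family = "GH13",
                                                        n_member_mags = 10,
                                                        members_per_mag = 1,
                                                        n_blocks = 1,
                                                        ec = "3.2.1.1")),
               "n_member_mags")
  expect_error(community_spec(decoy_rate = 2), "decoy_rate")
  expect_error(community_spec(block_peptide_length = c(3, 5)), "block_peptide_length")
})

test_that("planted peptides survive digestion and the empirical filters intact", {
  sim <- tiny_community(seed = 5)
  planted <- sim$manifest$planted
  expect_true(all(nchar(planted$peptide) >= 6 & nchar(planted$peptide) <= 25))
  expect_false(any(grepl("[MC]", planted$peptide)))
  for (i in seq_len(nrow(planted))) {
    seq <- sim$proteins$sequence[sim$proteins$protein_id == planted$protein_id[i]]
    peps <- tryptic_digest(seq)
    expect_true(planted$peptide[i] %in% peps)
    expect_true(planted$peptide[i] %in% filter_peptides(peps))
  }
})

test_that("planted blocks sit beyond the 24-residue trim", {
  sim <- tiny_community(seed = 9)
  planted <- sim$manifest$planted
  for (i in seq_len(nrow(planted))) {
    seq <- sim$proteins$sequence[sim$proteins$protein_id == planted$protein_id[i]]
    trimmed <- trim_n_terminus(seq, 24)
    expect_true(planted$peptide[i] %in% tryptic_digest(trimmed))
  }
})

test_that("decoy_rate 1 plants every block in the background too", {
  spec <- community_spec(n_mags = 6,
                         families = tibble::tibble(family = "GH13", n_member_mags = 3,
                                                   members_per_mag = 1, n_blocks = 2,
                                                   ec = "3.2.1.1"),
                         background_per_mag = c(4, 6),
                         protein_length = c(80, 120),
                         decoy_rate = 1, seed = 3)
  sim <- simulate_community(spec)
  expect_equal(nrow(sim$manifest$decoys), 2)
  for (i in seq_len(nrow(sim$manifest$decoys))) {
    d <- sim$manifest$decoys[i, ]
    seq <- sim$proteins$sequence[sim$proteins$protein_id == d$protein_id]
    expect_true(d$peptide %in% tryptic_digest(seq))
  }
})

test_that("the same seed reproduces the community byte-for-byte on disk", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_community(tiny_community(seed = 17), d1)
  write_community(tiny_community(seed = 17), d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_equal(f1, f2)
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f2))
  expect_equal(unname(h1), unname(h2))
  # a different seed changes sequences but not the schema
  d3 <- withr::local_tempdir()
  write_community(tiny_community(seed = 18), d3)
  expect_equal(sort(list.files(d3, recursive = TRUE)), f1)
  expect_false(all(unname(tools::md5sum(file.path(d3, f1))) == unname(h1)))
})

test_that("single-tool members are discarded by consensus and mask their peptides", {
  spec <- community_spec(n_mags = 8,
                         families = tibble::tibble(family = "GH13", n_member_mags = 6,
                                                   members_per_mag = 1, n_blocks = 1,
                                                   ec = "3.2.1.1"),
                         background_per_mag = c(4, 6),
                         protein_length = c(80, 120),
                         single_tool_rate = 0.5, seed = 21)
  sim <- simulate_community(spec)
  asg <- suppressMessages(consensus_families(as_tool_annotations(sim$annotations)))
  members <- unique(sim$manifest$planted$protein_id)
  assigned <- intersect(members, asg$protein_id)
  expect_lt(length(assigned), length(members))
  if (length(assigned) > 0 && length(assigned) < length(members)) {
    # an unassigned member lands in the background and its planted peptide
    # is no longer family-unique
    res <- suppressMessages(
      select_family_peptides(sim$proteins, sim$annotations, "GH13"))
    expect_false(sim$manifest$planted$peptide[1] %in%
                   res$unique_peps$GH13$peptide)
  }
})

test_that("recovery report scores planted peptides and member coverage", {
  sim <- tiny_community(seed = 33)
  res <- suppressMessages(
    select_family_peptides(sim$proteins, sim$annotations, c("GH13", "GH3")))
  rep <- verify_recovery(sim$manifest, res$covers, res$unique_peps)
  expect_equal(nrow(rep), 2)
  expect_equal(rep$recall, c(1, 1))
  expect_equal(rep$n_members_covered, rep$n_members)
  expect_equal(lengths(rep$uncovered_members), c(0L, 0L))
})
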