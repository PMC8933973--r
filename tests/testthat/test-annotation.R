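ann_rows <- function(...) {
  rows <- list(...)
  tibble::tibble(
    protein_id = vapply(rows, `[[`, character(1), 1),
    hmmer = lapply(rows, function(r) r[[2]]),
    diamond = lapply(rows, function(r) r[[3]]),
    hotpep = lapply(rows, function(r) r[[4]])
  )
}

none <- character(0)

test_that("consensus rule: >=2 tools, HMMER priority, DIAMOND/Hotpep agreement", {
  rows <- ann_rows(
    list("p1", "GH13", "GH13", none),   # hmmer priority
    list("p2", none, "GH3", "GH3"),     # diamond/hotpep agreement
    list("p3", none, "GH3", "GH5"),     # disagreement -> discarded
    list("p4", "GH2", none, none),      # one tool -> discarded
    list("p5", none, none, none)        # never annotated
  )
  asg <- suppressMessages(consensus_families(rows))
  expect_equal(asg$protein_id, c("p1", "p2"))
  expect_equal(asg$family, c("GH13", "GH3"))
  expect_equal(asg$evidence, c("hmmer-priority", "diamond-hotpep-agreement"))
  expect_setequal(attr(asg, "discarded"), c("p3", "p4"))
})

test_that("consensus keeps all HMMER labels of multi-domain proteins", {
  rows <- ann_rows(list("p1", c("GH13", "CBM50"), "GH13", none))
  asg <- consensus_families(rows)
  expect_setequal(asg$family, c("GH13", "CBM50"))
  expect_true(all(asg$evidence == "hmmer-priority"))
})

test_that("consensus output is independent of row order", {
  rows <- ann_rows(
    list("p1", "GH13", "GH13", none),
    list("p2", none, "GH3", "GH3"),
    list("p3", "GT2", "GT2", "GT2")
  )
  a <- consensus_families(rows)
  b <- consensus_families(rows[c(3, 1, 2), ])
  attr(a, "discarded") <- attr(b, "discarded") <- NULL
  expect_equal(a, b)
})

test_that("census computes per-MAG percentages and per-phylum class proportions", {
  proteins <- tibble::tibble(
    protein_id = sprintf("p%02d", 1:120),
    mag_id = rep(c("m1", "m2"), c(100, 20)),
    sequence = "AAAA"
  )
  asg <- tibble::tibble(
    protein_id = c("p01", "p02", "p03", "p101"),
    family = c("GH13", "GH3", "GT2", "GH5"),
    evidence = "hmmer-priority"
  )
  tax <- tibble::tibble(mag_id = c("m1", "m2"), phylum = c("Firmicutes", "Bacteroidota"))
  cen <- cazyme_census(asg, proteins, tax)
  m1 <- cen$per_mag[cen$per_mag$mag_id == "m1", ]
  expect_equal(m1$n_proteins, 100)
  expect_equal(m1$pct_cazymes, 3.0)
  firm <- cen$per_phylum[cen$per_phylum$phylum == "Firmicutes", ]
  expect_equal(firm$proportion[firm$class == "GH"], 2 / 3)
  expect_equal(firm$proportion[firm$class == "GT"], 1 / 3)
  # proportions sum to 1 within each phylum
  sums <- tapply(cen$per_phylum$proportion, cen$per_phylum$phylum, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("census: degenerate all-GH community has GH proportion 1", {
  proteins <- tibble::tibble(protein_id = c("p1", "p2"), mag_id = "m1", sequence = "A")
  asg <- tibble::tibble(protein_id = c("p1", "p2"), family = c("GH13", "GH3_4"),
                        evidence = "hmmer-priority")
  tax <- tibble::tibble(mag_id = "m1", phylum = "Firmicutes")
  cen <- cazyme_census(asg, proteins, tax)
  expect_equal(cen$per_phylum$class, "GH")
  expect_equal(cen$per_phylum$proportion, 1)
})

test_that("census rejects assignments for unknown proteins", {
  proteins <- tibble::tibble(protein_id = "p1", mag_id = "m1", sequence = "A")
  asg <- tibble::tibble(protein_id = "ghost", family = "GH13", evidence = "hmmer-priority")
  expect_error(cazyme_census(asg, proteins), "not present")
})

test_that("target/background split partitions the community with subfamily collapse", {
  proteins <- tibble::tibble(protein_id = sprintf("p%d", 1:10), mag_id = "m1",
                             sequence = "AAAA")
  asg <- tibble::tibble(
    protein_id = c("p1", "p2", "p3"),
    family = c("GH13", "GH13_20", "GH3"),
    evidence = "hmmer-priority"
  )
  parts <- split_target_background(proteins, asg, "GH13")
  expect_setequal(parts$targets$protein_id, c("p1", "p2"))
  expect_equal(nrow(parts$background), 8)
  expect_length(intersect(parts$targets$protein_id, parts$background$protein_id), 0)
  expect_setequal(c(parts$targets$protein_id, parts$background$protein_id),
                  proteins$protein_id)
})

test_that("multi-family protein is a target, never background, for the target family", {
  proteins <- tibble::tibble(protein_id = c("p1", "p2"), mag_id = "m1", sequence = "A")
  asg <- tibble::tibble(protein_id = c("p1", "p1"), family = c("GH13", "GH3"),
                        evidence = "hmmer-priority")
  parts <- split_target_background(proteins, asg, "GH13")
  expect_equal(parts$targets$protein_id, "p1")
  expect_equal(parts$background$protein_id, "p2")
})

test_that("split errors on a family with zero targets", {
  proteins <- tibble::tibble(protein_id = "p1", mag_id = "m1", sequence = "A")
  asg <- tibble::tibble(protein_id = "p1", family = "GH13", evidence = "hmmer-priority")
  expect_error(split_target_background(proteins, asg, "GH99"), "No target proteins")
  expect_error(split_target_background(proteins, asg, "bogus"), "valid CAZy")
})

test_that("family label helpers collapse subfamilies and classify classes", {
  expect_equal(collapse_subfamily(c("GH13_20", "GH3", "CBM50")),
               c("GH13", "GH3", "CBM50"))
  expect_equal(family_class(c("GH13", "GT2", "PL9", "CE1", "AA3", "CBM50",
                              "SLH", "cohesin")),
               c("GH", "GT", "PL", "CE", "AA", "CBM", "cohesin/SLH", "cohesin/SLH"))
  expect_error(family_class("XYZ1"), "Unrecognised")
})
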