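---
title: "Selecting family-unique tryptic peptides from MAG communities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting family-unique tryptic peptides from MAG communities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepcover)
library(dplyr)
```

## The problem

Targeted metaproteomics of a microbial community (for instance an anaerobic
digester dominated by carbohydrate-degrading bacteria) needs a small panel of
peptides that a mass spectrometer can monitor to quantify a *function* —
say, glycoside hydrolase (GH) family 13 amylases — rather than any single
protein. Because enzyme families share conserved sequence blocks, many family
members share identical tryptic peptides. pepcover finds, for each CAZyme
family of interest, the peptides that (a) occur in family members, (b) occur
nowhere else in the community's predicted proteome, and (c) jointly cover as
many family members as possible with as few peptides as possible.

The pipeline has four stages, each exposed as ordinary functions over
tibbles:

1. **Consensus annotation.** dbCAN2-style output from three annotation tools
   (HMMER, DIAMOND, Hotpep) is reduced to consensus CAZyme family calls:
   only proteins annotated by at least two tools are considered; HMMER
   labels take priority; failing HMMER, the DIAMOND/Hotpep intersection is
   used; otherwise the protein is discarded (`consensus_families()`).
2. **Peptidome construction.** For a target family, member proteins are
   deduplicated at 100% identity (exact duplicates and contained fragments
   removed, emulating CD-HIT's removal of partial gene calls), trimmed of
   their first 24 N-terminal residues, digested in silico with trypsin, and
   filtered to 6–25-residue peptides free of Met/Cys and ambiguous residues
   (`target_peptidome()`). All remaining community proteins form the
   background, digested with no trimming or filtering
   (`background_peptidome()`).
3. **Uniqueness.** A target peptide is family-unique iff its exact tryptic
   sequence never occurs in the background peptidome
   (`unique_target_peptides()`).
4. **Greedy minimum cover.** Peptides are ranked by the number of
   not-yet-covered member proteins they map to; the largest group is
   selected, its proteins are removed from all remaining peptides' sets,
   peptides with emptied sets are dropped, and the process repeats until
   every coverable protein is covered (`greedy_min_cover()`). The result is
   read out as coverage curves (`coverage_curve()`), EC-number groupings
   (`group_by_ec()`) and phylum compositions (`group_by_phylum()`).

## Model assumptions

* **Trypsin specificity** is taken as cleavage C-terminal to K or R except
  before P, with zero missed cleavages — the behaviour of Unipept's
  `prot2pept`. Real digests contain missed cleavages and semi-tryptic
  species; panels derived here are conservative in that a peptide's
  uniqueness is judged on the fully tryptic peptidome only.
* **The N-terminal trim is positional, not predictive.** Removing a fixed
  24 residues is a surrogate for signal-peptide cleavage; it avoids
  targeting maturation regions without running a predictor, at the cost of
  discarding genuine N-terminal peptides of cytoplasmic proteins.
* **Uniqueness is exact string identity.** By default Ile and Leu are
  distinct residues. Since mass spectrometry cannot distinguish them,
  `il_equivalence = TRUE` folds I into L in both target and background
  peptidomes before comparison; this is the setting to use when designing a
  real acquisition method.
* **The background is digested raw** — untrimmed and unfiltered. A peptide
  must be absent from *every* tryptic fragment of the background, including
  short and Met/Cys-containing ones. This makes uniqueness strictly harder
  than if the background were filtered, which is the safe direction for
  assay design.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `trim` | 24 | residues | positional signal-peptide surrogate on target seeds |
| `min_len`–`max_len` | 6–25 | residues | detectable, identifiable tryptic peptides on triple-quad/Orbitrap instruments |
| `excluded_residues` | M, C | — | residues prone to artifactual oxidation/alkylation |
| `il_equivalence` | FALSE | — | exact comparisons by default; enable for instrument-facing panels |
| `cutoffs` | 10, 50, 100, 200 | peptides | coverage-curve read-outs at realistic panel sizes |

Subfamily labels (`GH13_20`) are collapsed to their parent family for
targeting and never appear as separate targets: panels are designed per
family, and a subfamily member's peptides must not be treated as background
for its own family. A multi-domain protein carrying several families is a
target in each of them and enters no background of a family it carries —
the conservative reading of per-family removal, preventing a protein's own
peptides from masking themselves.

## Numerical and tie-break choices

* **Greedy ties** (several peptides covering equally many proteins) are
  broken by the lexicographically smallest peptide string. Any tied choice
  is equally good for coverage; a deterministic rule makes results
  reproducible and order-independent, which the tests assert.
* **Deduplication ties** (identical sequences) retain the record with the
  lexicographically smallest protein id; the longest sequence always
  represents a containment cluster.
* **Degenerate inputs**: proteins shorter than the trim contribute no
  peptides; if an entire target set does so, peptidome construction raises
  an explicit empty-peptidome error rather than returning silence. A family
  with no unique peptides is reported (`status = "empty-result"`, exit code
  3 from the CLI) with its residual protein list still written. Proteins
  with zero unique peptides are never silently dropped: they appear in the
  cover's `residual` attribute and depress the coverage percentages.
* **Phylum panel sizes** (`peptides_to_cover_taxon()`) default to the
  ranked-prefix convention — the number of top-ranked family-wide peptides
  needed before all of a phylum's covered proteins have appeared — because
  the family-wide list is what a practitioner would deploy, and its groups
  may mix taxonomic origins. A `mode = "restricted"` alternative re-runs
  the greedy cover on the phylum's proteins alone, yielding the smaller
  phylum-specific panel; both are exposed because either convention is
  defensible.
* **Ambiguous residues** (X, B, Z, U) disqualify a peptide: a peptide whose
  sequence is not fully determined cannot be synthesised as a standard.

## What the synthetic generator emulates — and what it does not

`simulate_community()` builds a community of MAG proteomes in which each
planted family's members share conserved blocks against an i.i.d. random
background. Residues are drawn with K+R ≈ 11%, giving a mean tryptic
peptide length of about 9, so filter pass rates resemble real proteomes.
Planted blocks are constructed as K/R + peptide + G and inserted after
position 24, guaranteeing that digestion emits the planted peptide intact,
that the empirical filters retain it, and that trimming cannot delete it.
`decoy_rate` re-inserts blocks into background proteins to destroy
uniqueness on demand; `single_tool_rate` under-annotates members so the
consensus discard rule (and the resulting self-masking, when a discarded
member falls into the background) can be exercised.

The default spec — 50 MAGs over three phyla, three GH families with 20
member MAGs each and one planted block, 20–40 background proteins of
120–400 residues per MAG — is the study condition used by the test suite
and the acceptance script; it is small enough to run in seconds yet large
enough that uniqueness filtering is non-trivial (hundreds of incidental
unique peptides arise from random member sequence).

What the generator does **not** model: phylogenetic correlation between
background proteins (real backgrounds contain homologous non-family
proteins that erode uniqueness far more than i.i.d. sequence does), partial
and fragmented gene calls (deduplication is exercised by construction in
tests instead), MAG contamination, and any peptide detectability or
retention-time behaviour. Passing tests therefore demonstrate the
*logic* of the pipeline — consensus, partitioning, digestion, uniqueness,
cover optimality properties — not the peptide yields to expect on a real
1400-genome community, which are set by sequence conservation structure
the simulator deliberately does not imitate.

## Validation strategy

The test suite checks the implementation against independent oracles built
on different routes: tryptic digestion against a regex lookaround split
(1000 random sequences, plus concatenation identity and idempotence);
every greedy step against a per-step maximisation replay and the final
size against exhaustive subset search (`brute_force_min_cover()`, random
instances up to 12 peptides × 15 proteins); uniqueness safety (no selected
peptide in the background peptidome) across decoy-laden communities; and
planted-peptide recovery on the default community (recall 1 with no
decoys; zero planted selections at `decoy_rate = 1`). Instance sizes were
chosen as the largest at which the exhaustive oracle is still exact and
fast; they are stated here as the package's validation conditions.

## Known limitations

* Greedy set cover is a ln(n)-approximation; on adversarial instances it
  can exceed the optimum (the tests only require it never to beat the
  exhaustive bound and to maximise each step). For the group structures
  conserved blocks produce, it is typically optimal or near-optimal.
* `dedup_100()` is a quadratic containment scan; it is ample for
  family-sized target sets (tens to hundreds of seeds) but is not meant
  for community-scale deduplication.
* The EC and taxonomy groupings are descriptive tallies over the covered
  sets; no statistical enrichment is attempted.
* A peptide unique in the *predicted* proteome may still be produced by
  unbinned or unassembled community members; uniqueness is always relative
  to the supplied FASTA universe.
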