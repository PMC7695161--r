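---
title: "Reassembling full-length COI barcodes from sheared short reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reassembling full-length COI barcodes from sheared short reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shearcoi)
```

## The problem

The ~710 bp cytochrome c oxidase subunit I (COI) fragment amplified by the
universal Folmer primers LCO1490/HCO2198 is the standard animal barcode, but
it is longer than the reads of the dominant short-read sequencing platforms.
`shearcoi` implements the *shear-and-reassemble* strategy for eDNA
metabarcoding: each amplicon pool is treated as a collection of miniature
genomes, randomly sheared to 250–300 bp, sequenced with 2×150 bp paired-end
chemistry, and the full-length barcode is reconstructed computationally
before OTU clustering and taxonomic assignment.

The package provides both the analysis pipeline and a ground-truthed
simulator of the wet-lab protocol, so every stage can be tested against
known inputs.

## Pipeline model and assumptions

1. **Quality control** (`trim_reads`). Leading/trailing bases below a Phred
   floor are removed, read suffixes matching an adapter prefix over at
   least 8 bp are clipped, and pairs with a mate shorter than `min_len`
   are dropped whole. Dropping at pair level (both mates or neither) keeps
   the assembler contract simple; singleton handling is otherwise an
   arbitrary choice.
2. **Assembly** (`assemble_reads`). A de Bruijn graph over both mates and
   their reverse complements at a single odd k (default 31). Cleaning is
   standard at this scale: k-mers observed once are dropped when the median
   k-mer depth is at least 10×, dead-end branches shorter than 2k are
   pruned, and parallel paths with identical flanking junctions differing
   by ≤ 2 substitutions are collapsed onto the deeper branch. Maximal
   unbranched paths ≥ `min_contig_len` (default 200 bp) become contigs,
   reported in canonical orientation (the lexicographically smaller of a
   sequence and its reverse complement) so results are independent of read
   strand and input order. A single k suffices at barcode scale and keeps
   the assembler auditable against brute-force expectations; no multi-k
   iteration is attempted.
3. **Map-back QC** (`map_back`). A pair is *properly mapped* when both
   mates place on the same contig (k-mer seeded, ungapped verification
   with soft-clipping at contig ends) at ≥ 90% identity over the aligned
   portion, in opposing orientations, with an implied fragment length
   within the shearing range widened by 50 bp. The definition is spelled
   out because published pipelines usually inherit it implicitly from an
   aligner's "proper pair" flag.
4. **Length filter** (`length_filter`). Assemblies longer than 712 bp are
   artefacts or non-target sequences (the theoretical primer-to-primer
   product is ~710 bp). The cutoff keeps `length <= 712`; where the
   source material is ambiguous between 712 and 713 bp conventions, the
   methods-text boundary (exceeding 712 bp is removed) wins.
5. **Dereplication and OTUs** (`dereplicate`, `cluster_greedy`,
   `cluster_consensus`). Identical sequences (after canonical orientation)
   collapse into unique features carrying replicate counts; greedy centroid
   clustering scans features by decreasing size and joins the first
   centroid at ≥ 98% global-alignment identity, comparing both strands
   (canonical orientation can flip between near-identical sequences when a
   mutation falls in the lexicographically deciding prefix, so strand is
   resolved at comparison time and members are stored in centroid
   orientation). Identity is *matching
   columns / alignment columns including gaps* — one of several
   conventions; it is stated explicitly because cluster membership depends
   on it. Consensus is the size-weighted column majority over
   member-to-centroid alignments, ties resolved toward the centroid.
6. **Chimera screen** (`flag_chimeras`). Reference-based: a feature whose
   two halves best-match references that disagree at class rank or above
   (each half at ≥ 85% identity) is flagged. This reuses the half-split
   mechanism of the validation campaign rather than introducing an
   abundance-based de novo detector.
7. **Taxonomic search and LCA** (`search_refdb`, `lca_assign`). Exact-match
   seeds (28 bp in `"high-identity"` mode, 11 bp in `"sensitive"` mode —
   chosen to reproduce the qualitative sensitivity gap between
   highly-similar and somewhat-similar search programs) on both strands,
   extended by local alignment (+1/−2, gap 2/1), with Karlin–Altschul
   e-values `E = K·m·n·exp(−λS)` (λ = 1.28, K = 0.46; these are the
   standard constants for this scoring and are configurable). Hits are
   kept at ≥ 70% identity and e ≤ 1e−5; the four best are retained. The
   LCA is a strict consensus: the deepest rank on which *all* retained
   hits agree, over a fixed six-rank ladder (phylum…species). No hits →
   `"unknown"`; hits conflicting already at phylum →
   `"unknown-eukaryotic"`. A majority-vote LCA with a configurable
   threshold is a known alternative; strict consensus is the simplest
   defensible reading and is what the validation procedures assume.
8. **Summaries** (`rank_summary`, `diversity_indices`). Rank-count tables
   count distinct taxa whose assignment terminates exactly at each rank,
   per phylum-level group, with row and grand totals. Diversity indices
   are the plug-in forms: Shannon H in natural log, Simpson dominance
   D = Σp², complement I = 1 − D, reciprocal R = 1/D, and Pielou evenness
   J = H/ln S. The plug-in (not bias-corrected) Simpson form is used
   because the identities I = 1 − D and R = 1/D then hold exactly, which
   is how published index tables of this form are internally consistent;
   published (H, J) pairs imply ln-based evenness at near-integer richness
   (16 and 22), supporting the natural-log convention. Community-level
   indices default to OTU sizes as categories.

## The simulator: what it emulates and what it does not

`evolve_references` grows a balanced taxonomic tree by substitution-only
mutation from one random ancestor (random padding, forward primer site,
659 bp insert, reverse-complement reverse primer site, random padding;
830 bp total, amplicon 710 bp). `divergence_per_rank[r]` is the expected
pairwise divergence of two leaves splitting at rank r; defaults
(0.30, 0.20, 0.14, 0.10, 0.06, 0.03 for phylum…species) follow typical COI
divergence structure. Indels are excluded so that identity is unambiguous —
none of the downstream methods depends on indel realism. Primer-binding
regions mutate at 5% of the genome-wide rate and the three 3′-clamp bases
not at all: universal primers target conserved sites, and a clamp mismatch
would abort extension. In-silico PCR allows 3 substitutions per binding
site outside the clamp, mimicking degenerate-primer tolerance.

Abundances are log-normal around equimolar with `sdlog = 0.35`: the
emulated protocol pools amplicons at equimolar concentration, so only
pipetting/amplification noise remains. Fragment lengths are uniform over
250–300 bp (sonication physics is not modelled), fragment start positions
uniform, substitution errors i.i.d. at the configured rate, and quality
strings encode that rate. Coverage is community-wide: fragments =
coverage × total amplicon length / mean fragment length.

Not modelled: PCR chimera formation, copy-number variation, quality-score
decay along reads, amplification bias across taxa, and indel errors.
Passing tests therefore demonstrate the *computational* correctness of the
pipeline on communities with these properties, not robustness to every
artefact of real sequencers.

## Numerical choices and degenerate inputs

* Median k-mer depth for the singleton cutoff is instance-weighted
  (median over k-mer occurrences): at realistic error rates most *distinct*
  k-mers are singleton errors, and a median over distinct k-mers would
  never reach the 10× threshold that the cutoff is meant to detect.
* Ties in greedy clustering (equal feature sizes) break lexicographically;
  consensus ties break toward the centroid; search ties (equal raw score)
  break by subject identifier, making results invariant to database order.
* `split_halves` splits ≥ 400 bp sequences at the midpoint with no
  overlap; shorter sequences get 25 bp of extension per half (50 bp
  overlap) so each half retains enough signal to be searched — the
  "small overlap" is quantified here as a single parameter because no
  number is inherited from the protocol being emulated.
* Amplicons shorter than the minimum fragment length shear to whole-length
  fragments and are flagged; fragments shorter than the read length yield
  full-fragment mates; empty inputs yield empty outputs everywhere except
  `map_back`, where an empty contig set is an error (there is nothing to
  map against).

## Design decisions that were genuinely open

* **Chimera donor rule.** Synthetic chimeras concatenate 2–3 fragments
  (150–400 bp, ≤ 712 bp total) from donors that are pairwise different at
  phylum level when the database has ≥ 2 phyla (falling back to class
  level otherwise), mirroring the arthropod-plus-vertebrate construction
  this test emulates. With a six-rank ladder starting at phylum, a
  same-phylum cross-class chimera would legitimately receive a phylum-rank
  LCA rather than an unknown label; crossing phyla makes "all chimeras
  unknown" a property of the method, not of tuning. Three-fragment
  chimeras are only built when three distinct groups exist.
* **Half-split concordance denominator.** Whether queries with a no-hit
  half belong in the denominator is unspecified in the protocol being
  emulated; the report carries both conventions (`fraction_top4` over all
  queries and `fraction_top4_with_hits` over queries with hits).
* **Taxonomy file dialect.** A plain 7-column TSV (id + six ranks,
  truncation only as a suffix) stands in for whatever format a curated
  local database uses; domain/kingdom are deliberately not ranks, with
  `"unknown-eukaryotic"` as a label instead.

## Problem sizes used in tests

The packaged checks run on desk-scale inputs chosen to exercise every code
path: a 16-reference database (2 phyla × 2 classes × 2 orders × 2 genera)
for search/LCA/validation checks, a 10-species community across 5 phyla at
30× coverage and 0.5% substitution error for assembly and map-back checks,
100 injected chimeras for the chimera campaign, and 1000 random count
vectors for the diversity identities. Dataset-dependent quantities from any
particular survey (raw read counts, absolute contig/feature/cluster counts,
observed mean hit identity, the exact concordance percentage of a real
dataset) are functions of that dataset and are not reproduced here; the
corresponding *mechanisms* are exercised as properties (concordance = 1 on
verbatim references and 0 on cross-phylum splices, all cross-phylum
chimeras labelled unknown, and so on).

## Known limitations

* Single-k de Bruijn assembly fragments when the community contains taxa
  whose barcodes share 31-mers (roughly, pairwise divergence below ~10%,
  e.g. congeneric species): shared runs create junctions that break
  unbranched paths. This is a property of the graph, not a bug; the
  length-bottleneck filter and map-back QC behave as expected on such
  fragmented assemblies, but full-length recovery of near-identical taxa
  requires either longer k-mers than the read length supports or paired-end
  scaffolding, which is out of scope.
* The strict equal-weight LCA is conservative in sparse databases: a query
  whose top hits span several genera is truncated to family or above even
  when one hit is clearly best. This mirrors the behaviour of
  last-common-ancestor assignment with incomplete references.
* E-values use fixed Karlin–Altschul constants rather than
  composition-adjusted ones; they are comparable within a run, not
  calibrated across scoring schemes.
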