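---
title: "Two-tier barcode verification: model, rules and synthetic design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-tier barcode verification: model, rules and synthetic design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liriopogon)
```

## The identification problem

*Liriope* and *Ophiopogon* are morphologically similar groundcover genera
whose cultivated accessions often cannot be told apart without flowering
material. The pipeline identifies each accession molecularly from two
standard plant barcodes — the plastid rbcL gene and the nuclear ribosomal
ITS region — and compares the result against the accession's recorded
label. rbcL is slowly evolving and works as a discrete SNP key; ITS is
faster evolving and supports species-level placement on a phylogeny. The
two tiers are deliberately redundant: the plastid and nuclear genomes are
inherited differently, so concordance between them is itself evidence (and
discordance is flagged, as a possible hybridization signal, rather than
silently resolved).

## Tier one: the rbcL haplotype key

The packaged panel (`load_panel()`) defines 15 informative SNP positions in
a 900 bp rbcL reference (the rbcLa barcode sub-region is columns 1–500 and
contributes positions 172, 216, 392 and 431; the rest lie in the rbcLb
sub-region). Six named haplotypes (Types 1–6) each fix one base per
position; Type 2 is the consensus. Relative to Type 2, the panel enforces
at load time: Type 1 differs by 4 SNPs (3 unique variants), Type 3 by 2
(1 unique), Type 4 by 2 (both unique), Type 5 by 3 (all unique), Type 6 by
7 (5 unique), and position 431 is G in every *Ophiopogon* row and A in the
*Liriope* row. These published per-type counts only close arithmetically
over 15 distinct positions if "unique" is read per *variant* rather than
per *position*: two pairs of haplotypes share a position while carrying
different substituted bases there, and two variants are shared outright.
The packaged cell values realize exactly that reading; any transcription
change that breaks a count fails validation loudly.

A query is globally aligned to the reference (Needleman–Wunsch, affine
gaps; match +1, mismatch −1, gap open 10, gap extension 1 — the gap costs
mirror the Clustal-style parameters used for the original alignments, and
the simple match/mismatch scores are a documented choice, configurable in
`align_to_reference()`). Queries under 70% identity over their covered
reference positions are rejected as wrong-locus. The haplotype call is the
Hamming-nearest panel row, with IUPAC ambiguity codes counting as matches
when their base set contains the haplotype base and gaps always counting as
mismatches. `max_distance` defaults to 1: collection sequences matched
published haplotypes exactly, so one tolerated mismatch (flagged `near`)
only absorbs a Sanger-style miscall; ties are reported as `ambiguous`,
never broken silently. The genus is read from position 431 alone, even
when the full haplotype is ambiguous.

## Tier two: ITS phylogeny and the SNP triplet

The original analysis used a maximum-likelihood tree under the Kimura
2-parameter (K2P) model in an external GUI package. Because every
identification decision consumes only *clade membership* — never branch
lengths or likelihoods — the package estimates the tree with
neighbor-joining on K2P distances, which is deterministic, fast and fully
implementable in-repo; this deviation is deliberate and documented here.

* **K2P distance** (`k2p_distance()`, `k2p_matrix()`): with transition
  proportion $P$ and transversion proportion $Q$ over the $L$ sites where
  both sequences have unambiguous bases (pairwise deletion; complete
  deletion is available by pre-filtering columns),
  $d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$. Saturation
  ($1-2P-Q \le 0$ or $1-2Q \le 0$) is a hard error, not an `NA`.
* **Neighbor-joining** (`nj_tree()`): standard Q-criterion agglomeration.
  Ties in Q are broken by the lowest (row, column) pair so results are
  platform-reproducible; negative branch lengths are clamped to zero with
  the total deficit recorded in `attr(tree, "clamped")`; zero-length
  internal edges are collapsed to polytomies (an all-zero matrix therefore
  yields a star, and groups of identical sequences form honest polytomies).
* **Bootstrap and consensus** (`bootstrap_consensus()`,
  `majority_consensus()`): alignment columns are resampled with
  replacement under a caller-supplied seed; bipartitions present in at
  least the threshold fraction (default 0.5 — at *exactly* the threshold a
  split is kept, matching the "collapse below 50%" convention) form the
  majority-rule consensus, with supports attached as percentages. The
  default of 100 replicates keeps desk runs fast; raise `bootstrap` to
  1000 for publication-grade supports.
* **Clade assignment** (`assign_clade()`): supports are mapped onto the
  point-estimate NJ tree (`map_supports()`), which, unlike a strict
  consensus topology, has branch lengths; the query's label is that of the
  smallest supported clade containing it and at least two same-labelled
  references. Supported but mixed-label surroundings give `unassigned`;
  when no supported multi-reference clade contains the query at all, the
  nearest reference by patristic distance is used and flagged
  `low_confidence`. The consensus tree is still computed and written as an
  artifact.

*O. planiscapus* and *O. bodinieri* are barely separated by ITS distance,
so a three-SNP key at reference positions 46 (A/G), 231 (C/T) and 545
(C/T) decides between them: 3-of-3 matches call the species, 2-of-3 call
it flagged `partial`, anything else is `undetermined`
(`triplet_call()`). The published description does not state which allele
belongs to which species, so the orientation is panel *data* (marked
`synthetic` in the panel file), chosen once and used consistently by the
generator, the references and the tests.

## The decision rules

`identify_accession()` applies, in order: Type 6 → *Liriope*, species from
the ITS cluster (muscari vs spicata); Type 1 → *O. japonicus* (I); Type 5 →
*O. jaburan*; Type 3 → *O. planiscapus*, which the triplet must corroborate
(else `triplet_conflict`); Type 2 → resolved by ITS (B2 → *O. japonicus*
(II); B3 placement with a bodinieri triplet → *O. bodinieri*); Type 4 →
the panel's taxon, flagged `low_confidence`. Within subclade B3 the
triplet *overrides* tree placement on conflict — this encodes how the four
anomalously placed accessions in the source collection were resolved (Type
3 sequences placed in B3b were still called *O. planiscapus*; Type 2
sequences placed in B3a were still called *O. bodinieri*), and the flag
`triplet_overrides_placement` records every such override. A missing locus
degrades to a single-locus call, flagged, never dropped.

`status_of()` compares the identification with the synonym-normalized
label (`normalize_label()`; defaults: *L. exiliflora* → *L. muscari*,
*O. wallichianus* → *O. japonicus* — the latter is genuinely contested,
some treatments prefer *O. intermedius*; the table is an argument, and for
the reconstructed collection either choice yields the same status).
Subgroup numerals "(I)"/"(II)" and quoted cultivar epithets are ignored
for matching. A genus mismatch is always `genus_misid`, even when the
label was genus-only; a genus-only label resolved to species is
`newly_identified`.

## The synthetic collection: what it is and is not

No sequence data are downloaded; the generator states its world
explicitly:

* Backbones (900 bp rbcL, 600 bp ITS) are fixed synthetic sequences frozen
  in the panel file; only their diagnostic positions carry meaning.
* Each rbcL haplotype sequence is the backbone with that row's 15 bases
  substituted. Each ITS clade consensus carries a block of 12
  clade-private transitions (2% of the alignment — comfortably above the
  bootstrap noise floor at zero noise, yet within genus-level ITS
  divergence), both *Liriope* clades share a further 12-position genus
  block (making the genus monophyletic on the tree), and B3b additionally
  carries the bodinieri triplet. Three references per clade (the
  consensus plus two variants with 2 private substitutions each) give
  `assign_clade()` the ≥2 labelled references it requires.
* Noise (`generator_config()`): per-base substitutions, N injection and
  indels, all seeded, all in [0, 0.2], all off by default. With
  `protect_diagnostic = TRUE` noise spares panel, clade and triplet
  positions — emulating sequencing error without destroying signal; with
  protection off, noise can and occasionally does hit diagnostic
  positions, which is what the `near`/`ambiguous` haplotype flags are for.
* The packaged truth manifest reconstructs the 73 testable accessions of
  the source collection (46 *Liriope*-collection, 27 *Ophiopogon*). Rows
  named in the source narrative carry their reported label, haplotype and
  clade; rows only countable from category totals are filled to match
  those totals exactly and flagged `reconstructed=yes`. One narrative
  conflict is resolved in the fixture: the per-accession statements imply
  ten confirmed *Ophiopogon*-collection accessions while the printed
  totals (36 overall, 27 of them *Liriope*) leave room for nine, so one
  group-stated row (BTG_698) is demoted to a species-level
  misidentification with a reconstructed label. Similarly, the four
  anomalous tree placements cannot be realized by a zero-noise generator
  (synthetic sequences place in their species' true clade), so the
  override rule they motivated is exercised by dedicated unit tests on
  constructed evidence instead. `validate_truth_manifest()` re-derives
  all category totals from the fixture *before any sequence is generated*
  and refuses to run on a perturbed manifest.

A green acceptance run therefore establishes that the pipeline's calling,
placement and decision logic reproduce the published collection-level
outcome given each accession's reported haplotype/clade — not that the
packaged sequences match the (undeposited) real amplicons, and not that
the tree stage would survive real ITS length variation: the generator
produces no alignment-length polymorphism beyond its optional uniform
indel noise, and poor-quality traces are modelled only as N-rich input.

## Numerical and degenerate-input choices

Alignment identity floor 0.7 (wrong-locus guard); IUPAC-overlap scoring
in alignment (an N aligns as a match and is resolved downstream);
saturation and empty-overlap distance errors rather than NAs; NJ tie-break
and clamping as above; bootstrap splits tied at exactly the retention
threshold are admitted greedily in order of frequency then lexicographic
split key, so conflicting 50/50 splits resolve deterministically; Newick
output roots arbitrarily at the final agglomeration with supports as
internal node labels. Reports are byte-deterministic for fixed inputs and
seed.

## Scaled test budgets

The stated noise-recovery design (100 seeds over the full collection at 1%
protected noise, ≥99% identity recovery) is split to fit a desk-scale test
budget without changing thresholds: the rbcL haplotype half runs over 100
seeds (one accession per species per seed), and the full two-locus
identification runs over 25 seeds on a stratified 18-accession subsample
with bootstrap 10. Both are in the shipped test suite.

## Known limitations

Coordinates are package-defined (1-based in the packaged references); real
amplicons must be mapped through `align_to_reference()`, not indexed
directly. The panel cell values beyond the validated counts are a
reconstruction, as is the triplet orientation. No multiple sequence
alignment, no maximum-likelihood or rate-heterogeneity models, no
chromatogram handling, and no hybrid model beyond the
`genus_discordance` flag.
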