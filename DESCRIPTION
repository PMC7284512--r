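Package: liriopogon
Title: Two-Tier DNA Barcode Verification for Liriope and Ophiopogon Collections
Version: 0.1.0
Authors@R:
    person("Biomolecular", "Verification", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a two-tier DNA barcode identification pipeline for
    living collections of Liriope and Ophiopogon ("Liriopogon") plants. Tier
    one calls a plastid rbcL SNP haplotype (Types 1-6) against a packaged
    diagnostic panel, including a genus-diagnostic G/A site; tier two places
    nuclear ribosomal ITS amplicons on a neighbor-joining tree built from
    Kimura 2-parameter distances with seeded bootstrap and majority-rule
    consensus, assigns each query to a labelled reference clade, and evaluates
    a three-SNP ITS key separating O. planiscapus from O. bodinieri. A
    decision engine combines the evidence into per-accession identifications
    (confirmed, newly identified, species- or genus-level misidentification)
    and collection-level tallies. A seeded synthetic-data module generates
    two-locus amplicons for any panel haplotype and clade, and reconstructs a
    73-accession reference collection so the whole pipeline is testable
    without external sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
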