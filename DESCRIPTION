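Package: shearcoi
Title: Shear-and-Reassemble COI Metabarcoding Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs full-length (~710 bp) cytochrome c oxidase subunit I
    (COI) barcodes from short shotgun reads of randomly sheared amplicon pools,
    the "miniature genome" approach to eDNA metabarcoding. Provides a synthetic
    mock-community generator (taxonomy-structured reference evolution,
    in-silico PCR with the Folmer LCO1490/HCO2198 primers, sonication-style
    shearing, error-bearing 2x150 bp paired-end reads), read quality trimming,
    a small de Bruijn graph assembler with map-back quality control, length
    filtering, dereplication, reference-based chimera screening, greedy 98%
    centroid OTU clustering with consensus extraction, seeded local-alignment
    taxonomic search with Karlin-Altschul e-values in two sensitivity modes,
    strict LCA consensus rank assignment, half-split concordance and
    chimera-injection validation procedures, alpha-diversity indices, and
    taxonomic rank summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    tools,
    utils,
    vegan,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
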