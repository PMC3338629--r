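Package: cotaxa
Title: Clone-Library 16S rRNA Phylotyping and Provisional Oral Taxonomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building a reference taxonomy from 16S rRNA clone
    libraries, as used for the canine oral microbiome. Implements clone
    validation (trimmed-length filter and an end-divergence chimera test),
    greedy dual-threshold phylotype assignment into Canine Oral Taxa (COTs)
    with an incrementally growing full-length reference set, Jukes-Cantor
    distances with pairwise deletion, neighbor-joining trees with bootstrap
    support, a provisional six-rank taxonomy with novel-genus placeholders,
    phylum-by-primer summary tables, rank-abundance and coverage statistics,
    and cross-microbiome taxon sharing. Includes a ground-truthed synthetic
    16S community generator (primer bias, sequencing error, chimeras, short
    failed reads) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
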