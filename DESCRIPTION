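Package: clipmap
Title: Splice-Site RNA Maps and Alternative-Splicing Integration for eCLIP Peaks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream integration of eCLIP binding peaks with RNA-seq
    alternative-splicing calls: replicate-consensus peak merging with a
    2-of-N support rule, high-confidence enrichment filtering, genic
    annotation of peaks, splice-site-anchored input-normalised metagene
    binding maps, percent-spliced-in (delta-PSI) event classification and
    class-stratified composite occupancy maps, splice-site strength and
    exon-architecture comparisons, chi-squared gene-ontology enrichment and
    permutation-based protein-complex enrichment. Ships a deterministic
    synthetic-data generator that emulates the full input stack (annotation,
    stranded peak libraries with planted positional preferences, IP/input
    coverage, splicing event tables, GO and complex fixtures) so the whole
    pipeline can be exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
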