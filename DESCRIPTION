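Package: circulome
Title: Detection of Extrachromosomal Circular DNA from Tagmentation Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools for identifying extrachromosomal circular DNA (eccDNA) in
    paired-end tagmentation sequencing experiments. Tn5 transposase duplicates
    9 bp of target sequence at every insertion, so a circle cut exactly once
    carries the same 9-mer at the start of both mates of its read pair; the
    package detects this duplication signature, classifies reads over unique
    and repetitive genome space with a k-mer index and a focal-repeat span
    rule, and calls eccDNA-enriched genomic bins by exact binomial comparison
    of an enriched fraction against its matched total-genomic control.
    A topology-aware read simulator (circular and linear templates, Poisson
    tagmentation with target-site duplication, exonuclease-style removal of
    linear molecules) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    GenomicAlignments,
    Rsamtools,
    stats,
    tools,
    utils
Suggests:
    GenomicRanges,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
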