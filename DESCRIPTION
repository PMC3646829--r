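Package: asmrecon
Title: Reference-Based Assessment of De Novo Genome Assemblies from SOLiD Color-Space Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating de novo genome assemblies against a finished
    reference, built around short mate-paired SOLiD color-space read data.
    Provides a di-base color-space codec with csfasta/.qual input and output,
    quality-based read filtering regimes (unfiltered, undetermined-call removal,
    minimum quality value), an anchor-and-chain local aligner of scaffolds to a
    reference, assembly size statistics (N50, NG50, and R50, the NG50 of
    reference fragments covered by significant scaffold alignments),
    misarrangement classification (misjoins, inversions, deletions, insertions
    above a size threshold), small-indel accounting, per-gene reconstruction
    scoring with secondary-metabolite gene-cluster continuity testing, and a
    seeded synthetic-data generator (multi-chromosome genome with AT-rich
    centromeres and repeat-rich gene clusters, error-bearing scaffolds with a
    truth table, and mate-paired color-space reads) so the whole pipeline is
    testable without real sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
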