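Package: mixasm
Title: Reference-Free Reconciliation of Draft Bacterial Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Merges two or more draft bacterial assemblies without a
    reference genome. Terminal contig-contig alignments are cleaned by a
    five-rule filter, assembled into a weighted extension graph in which
    every legal gluing of contig extremities is a path, and a maximal
    independent set of longest In-to-Out paths is extracted (with strongly
    connected components expanded into their simple paths first). Paths are
    stitched into merged contigs, and elements largely contained in other
    elements are pruned through a coverage graph. Includes a synthetic
    fragmentation simulator, exact-overlap ground-truth alignments, a
    nucmer show-coords parser, fragmentation statistics (N50), and a small
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    igraph,
    jsonlite,
    methods,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
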