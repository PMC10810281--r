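Package: sortnscreen
Title: Sorted Transposon Insertion Screens: Simulation, Quantification and
    Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of sorted transposon insertion sequencing screens, in
    which a dense transposon mutant library carrying a fluorescent reporter is
    sorted by FACS into high, low and depleted fluorescence bins and insertion
    junctions are deep-sequenced per bin. Provides readers for per-base
    insertion plot files, genome FASTA and GFF3 annotation; reduction of
    per-base profiles to unique insertion sites and per-feature counts over a
    gene plus intergenic feature universe; a conditional negative-binomial
    exact test of each sorted bin against the depleted control with
    Benjamini-Hochberg correction and regulator calling; cross-screen overlap
    comparison; a synthetic sorted-library generator with planted regulator
    effects for ground-truth validation; and calculators for conjugation
    interference and phage efficiency-of-plating read-outs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    optparse
Config/testthat/edition: 3
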