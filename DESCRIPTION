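Package: sgnb
Title: Isoform-Level Differential Expression from RNA-Seq Without Isoform Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Splicing-graph negative binomial (SGNB) analysis of RNA-seq data.
    Reads are summarised into read types (ordered chains of non-overlapping exon
    IDs), read types that are always generated by the same set of isoforms are
    merged via a splicing graph, and each merged read-type group is tested for
    differential expression between two conditions with a negative binomial
    exact test based on quantile-adjusted conditional maximum likelihood
    dispersion estimation. Detects isoform switches that gene-level total-count
    tests miss, without requiring pre-specified isoform structures. Includes a
    mechanistic single-end read simulator and brute-force ground-truth oracles
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    edgeR,
    IRanges,
    GenomicRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
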