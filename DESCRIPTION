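Package: cnescan
Title: Phylogenetic Footprinting of Upstream Conserved Non-Coding Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects deeply conserved non-coding elements (CNEs) in the
    regions upstream of orthologous genes by exhaustive pairwise alignment of
    fixed-length sequence windows, with false-discovery control calibrated on
    randomly paired pseudo-orthologous sequences. Includes reciprocal-best-hit
    orthology assignment, upstream region extraction with truncation and
    removal rules, sigmoid scaling of window alignment scores into per-species
    conservation scores, combination across species into a combined
    conservation score, permutation-based coding-sequence filtering, and
    downstream characterization of the called elements: nucleotide
    composition, positional conservation relative to the translation start
    site, transcribed overlap by exact k-mer matching, RNA structure
    conservation via the structure conservation index with
    conservation-pattern-preserving column shuffling, and position weight
    matrix over-representation statistics against matched genomic controls.
    A synthetic cohort generator with planted conserved elements, repeats,
    hairpins and pseudo-ortholog pairings makes every stage testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
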