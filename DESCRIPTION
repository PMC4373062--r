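Package: ervclock
Title: Detection, LTR-Divergence Dating and Lineage Delimitation of
    Endogenous Retroviruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mines genomic contigs for proviruses flanked by long terminal
    repeats (LTRs), validates LTR hallmarks (TG...CA termini, the AATAAA
    polyadenylation signal, an AT-rich TATA-like stretch), quantifies coding
    decay of the internal gag-pol-env cassette as counts of nonsense and
    frameshift mutations against an intact reference, estimates insertion
    ages from 5'/3'-LTR divergence under Kimura's two-parameter model via
    T = D/(2R) over a panel of neutral substitution rates, and delimits ERV
    lineages by neighbor joining and single-linkage threshold clustering,
    with Gblocks-style alignment-block trimming and homology-hit curation.
    Ships a provirus simulator with recorded ground truth (age, rate, LTR
    coordinates, injected defects) so every stage is benchmarked without
    external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
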