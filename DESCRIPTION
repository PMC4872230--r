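Package: mirseed
Title: Small RNA Sequencing Analysis and Rule-Based miRNA Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing analysis toolkit for
    non-model organisms: clean-read filtering with per-category
    accounting, exact genome mapping, annotation triage against
    non-coding RNA references, rule-based novel and conserved miRNA
    identification driven by an internal RNA secondary-structure
    minimum-free-energy folding engine, miRNA family clustering with
    neighbor-joining trees and bootstrap support, positional-rule
    miRNA target prediction with cleavage versus translational
    inhibition classification, hypergeometric GO and KEGG term
    enrichment, and bipartite miRNA-target network export. A bundled
    synthetic-data generator produces seed-deterministic genomes,
    reads, ESTs, transcripts and annotation maps with planted ground
    truth so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    ape,
    igraph
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
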