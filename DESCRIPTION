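Package: ctsai
Title: Detection of Cell-Type-Specific Alternative Transcript Isoforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genes whose two transcript isoforms show opposite
    expression bias between two cell types (germ/gonidial versus somatic
    cells of Volvox carteri and similarly structured designs) from
    transcript-level FPKM tables. Implements the expression floor and
    isoform census, a three-stage filter cascade on per-isoform cell-type
    expression ratios and differential-expression p-values, quantitative
    read-density and relative-support curation checks on per-base coverage
    tracks, a screen for convergent overlapping antisense transcript pairs
    miscalled as isoforms, cross-species alternative-splicing conservation
    overlap on 1:1 ortholog maps, and a PFAM-domain screen classifying
    RNA-binding-protein genes by cell-type expression bias. A synthetic
    data module generates annotation, expression and coverage fixtures
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
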