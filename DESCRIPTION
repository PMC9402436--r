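Package: cnaphase
Title: Phased Copy-Number Evolution Analysis for Sparse Single-Cell
    Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing the ordered phases of copy-number
    evolution (loss of heterozygosity, deletion accumulation, whole-genome
    doubling, and post-doubling gains and amplifications) from sparse
    single-cell whole-genome sequencing bin counts.  Provides GC-bias
    correction, circular binary segmentation, quantal (least-squares
    integer) ploidy fitting, breakpoint-coincidence clonal phylogenetics
    with permutation-based false-discovery-rate clone calling, tracing of
    polyploid cells to rearranged diploid precursors, and population-level
    copy-number-alteration statistics (recurrent cores, gain/deletion
    frequency tracks, homogeneity scores, event-class enrichment tests).
    Includes a synthetic clonal-evolution generator so that every stage of
    the pipeline can be exercised and validated without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
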