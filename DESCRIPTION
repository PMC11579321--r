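Package: T2Tkit
Title: Toolkit for Curating and Evaluating Telomere-to-Telomere Genome Assemblies
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reusable implementations of the bespoke computational stages behind
    telomere-to-telomere (T2T) assembly curation of an acrocentric mammalian
    genome: trio k-mer read binning, rare-k-mer-scored gap filling, telomere
    detection and end patching, k-mer consensus quality (QV) and minimum unique
    k-mer (MUK) assessment, centromeric satellite monomer discovery, segmental
    duplication detection, previously-unresolved-region (PUR/NAR) comparison,
    and a variant-filtering plus windowed selection-scan pipeline. A synthetic
    genome generator with full ground truth (telomeres, satellite arrays,
    segmental duplications, gaps, trios, reads, and a two-population drift
    model with planted sweeps) makes the whole pipeline testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: GenomeAssembly, Sequencing, Alignment, PopulationGenetics, Coverage
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'T2Tkit-package.R'
    'asmcompare.R'
    'finishkit-gaps.R'
    'finishkit-polish.R'
    'finishkit-telomeres.R'
    'kmercore.R'
    'paf.R'
    'popscan.R'
    'repeatscape.R'
    'simforge.R'
    'utils.R'
    'vcfio.R'
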