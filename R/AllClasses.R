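#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @useDynLib T2Tkit, .registration = TRUE
NULL

## ---------------------------------------------------------------------------
## k-mer containers
## ---------------------------------------------------------------------------

#' Canonical k-mer count table
#'
#' Stores canonical (lexicographic minimum of a k-mer and its reverse
#' complement) k-mer counts. k-mers containing non-ACGT characters are never
#' counted. This table underpins hapmer extraction, trio read binning,
#' QV estimation, rare k-mer selection and MUK assessment.
#'
#' @slot k odd k-mer size.
#' @slot kmer character vector of canonical k-mers, sorted.
#' @slot count integer counts (all >= 1), parallel to `kmer`.
#' @seealso [countKmers()]
#' @export
setClass("KmerTable",
  representation(k = "integer", kmer = "character", count = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@k) != 1L || is.na(object@k))
      msg <- c(msg, "k must be a single integer")
    else if (object@k %% 2L == 0L)
      msg <- c(msg, "k must be odd (even k is ambiguous under canonicalization)")
    if (length(object@kmer) != length(object@count))
      msg <- c(msg, "kmer and count lengths differ")
    if (length(object@count) && any(object@count < 1L))
      msg <- c(msg, "counts must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' Parent-specific k-mer (hapmer) set
#'
#' k-mers observed in exactly one parent and at moderate depth in the child,
#' used to assign reads a parental origin.
#'
#' @slot parent `"paternal"` or `"maternal"`.
#' @slot k k-mer size.
#' @slot kmer canonical hapmer strings.
#' @slot dmin,dmax child-depth bounds applied during extraction
#'   (depth strictly greater than `dmin` and strictly less than `dmax`).
#' @export
setClass("HapmerSet",
  representation(parent = "character", k = "integer", kmer = "character",
                 dmin = "numeric", dmax = "numeric"),
  validity = function(object) {
    if (!object@parent %in% c("paternal", "maternal"))
      return("parent must be 'paternal' or 'maternal'")
    TRUE
  })

#' Merqury-style consensus quality report
#'
#' @slot perSeq per-sequence data.frame with columns `name`, `total`
#'   (assembly k-mers), `absent` (k-mers missing from the read table),
#'   `error` (per-base error estimate) and `qv`.
#' @slot total,absent genome-wide totals.
#' @slot errorRate genome-wide per-base error estimate.
#' @slot qv genome-wide QV (= -10 log10 error), capped at `cap` when no
#'   absent k-mers are observed.
#' @slot cap reporting cap.
#' @export
setClass("QVReport",
  representation(perSeq = "data.frame", total = "numeric", absent = "numeric",
                 errorRate = "numeric", qv = "numeric", cap = "numeric"),
  validity = function(object) {
    if (object@absent > object@total) return("absent k-mers exceed total")
    if (object@qv < 0) return("QV must be >= 0")
    TRUE
  })

## ---------------------------------------------------------------------------
## synthetic genome containers
## ---------------------------------------------------------------------------

#' Specification for a synthetic caprine-like genome
#'
#' Describes the features planted by [makeGenome()]: terminal telomere arrays,
#' near-end centromeric satellite arrays (monomer families of 816, 702 and
#' 22 bp, mirroring the SatI/SatII/SatIII unit lengths of goat centromeres),
#' segmental duplications, N-gaps and optional rDNA-like arrays. Coordinates
#' in the plant tables are 0-based half-open.
#'
#' @slot chromLengths named integer vector of chromosome lengths (bp).
#' @slot telomereCopies tandem copies of the telomeric 6-mer at each end.
#' @slot telomereMotif canonical telomere motif planted at the 5' end
#'   (its reverse complement caps the 3' end).
#' @slot centromeres data.frame: `chrom`, `start`, `monomerLength`,
#'   `copies`, `divergence` (per-copy i.i.d. substitution rate).
#' @slot sds data.frame of duplication plants: `srcChrom`, `srcStart`,
#'   `srcEnd`, `tgtChrom`, `tgtStart`, `divergence`.
#' @slot gaps data.frame of N-gap plants: `chrom`, `start`, `end`.
#' @slot rdna data.frame (possibly empty): `chrom`, `start`, `unitLength`,
#'   `copies`.
#' @slot seed integer seed driving all random choices.
#' @export
setClass("GenomeSpec",
  representation(chromLengths = "integer", telomereCopies = "integer",
                 telomereMotif = "character", centromeres = "data.frame",
                 sds = "data.frame", gaps = "data.frame", rdna = "data.frame",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (any(object@chromLengths <= 0L)) msg <- c(msg, "chromosome lengths must be > 0")
    if (is.null(names(object@chromLengths))) msg <- c(msg, "chromosomes must be named")
    if (nrow(object@centromeres) &&
        any(object@centromeres$divergence < 0 | object@centromeres$divergence >= 1))
      msg <- c(msg, "divergence rates must lie in [0, 1)")
    if (is.null(msg)) TRUE else msg
  })

#' Synthetic genome with ground-truth annotation
#'
#' @slot seqs named [Biostrings::DNAStringSet] of chromosome sequences.
#' @slot truth [GenomicRanges::GRanges] of planted features with metadata
#'   columns `label` (telomere/centromere/sd/gap/rdna) and `id`.
#' @slot seed seed used for generation.
#' @export
setClass("SyntheticGenome",
  representation(seqs = "DNAStringSet", truth = "GRanges", seed = "integer"))

#' A simulated father/mother/offspring trio
#'
#' Each parent carries two haplotypes derived from the base genome by planted
#' SNVs; the child is the byte-identical copy of one paternal and one maternal
#' haplotype.
#'
#' @slot father,mother lists of two named DNAStringSet haplotypes.
#' @slot childPaternal,childMaternal the child's two haplotypes.
#' @slot variants data.frame of planted SNVs: `parent`, `hap`, `chrom`,
#'   `pos` (1-based), `ref`, `alt`.
#' @slot hetRate per-bp heterozygosity used.
#' @slot choice integer(2): which paternal and maternal haplotype the child
#'   inherited.
#' @export
setClass("TrioHaplotypes",
  representation(father = "list", mother = "list",
                 childPaternal = "DNAStringSet", childMaternal = "DNAStringSet",
                 variants = "data.frame", hetRate = "numeric",
                 choice = "integer"))

#' Sequencing read profile
#'
#' @slot platform `"long"` or `"short"`.
#' @slot meanLength,sdLength read length distribution (bp); `sdLength = 0`
#'   gives fixed-length reads. The long-read default mean of 18,950 bp mirrors
#'   a typical HiFi length (N50 18.95 kb).
#' @slot subRate,insRate,delRate per-base error rates.
#' @slot depth target fold coverage.
#' @export
setClass("ReadProfile",
  representation(platform = "character", meanLength = "numeric",
                 sdLength = "numeric", subRate = "numeric", insRate = "numeric",
                 delRate = "numeric", depth = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@depth <= 0) msg <- c(msg, "depth must be > 0")
    rates <- c(object@subRate, object@insRate, object@delRate)
    if (any(rates < 0 | rates >= 1)) msg <- c(msg, "error rates must lie in [0, 1)")
    if (is.null(msg)) TRUE else msg
  })

#' Two-population drift model with planted sweeps
#'
#' Allele frequencies follow the Balding-Nichols model: an ancestral frequency
#' is drawn once per site and each population draws its frequency from a Beta
#' distribution with drift parameter F (the expected FST). Sweep intervals
#' multiply per-site expected heterozygosity in the target population by a
#' reduction factor.
#'
#' @slot sampleSizes integer(2) diploid samples per population.
#' @slot F numeric(2) drift parameters in [0, 1).
#' @slot nSites number of biallelic sites.
#' @slot sweeps data.frame: `chrom`, `start`, `end`, `factor`, `pop`.
#' @slot missingRate genotype missingness rate.
#' @export
setClass("PopulationModel",
  representation(sampleSizes = "integer", F = "numeric", nSites = "integer",
                 sweeps = "data.frame", missingRate = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(object@F < 0 | object@F >= 1)) msg <- c(msg, "F must lie in [0, 1)")
    if (any(object@sampleSizes < 2L)) msg <- c(msg, "sample sizes must be >= 2")
    if (nrow(object@sweeps) &&
        any(object@sweeps$factor <= 0 | object@sweeps$factor > 1))
      msg <- c(msg, "sweep factors must lie in (0, 1]")
    if (is.null(msg)) TRUE else msg
  })

## ---------------------------------------------------------------------------
## genotype matrix
## ---------------------------------------------------------------------------

#' Samples-by-sites genotype matrix
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] with one `"GT"` assay
#' (sites as rows, samples as columns; dosages 0/1/2 with NA for missing) and
#' a `population` column in `colData`.
#'
#' @export
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")
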