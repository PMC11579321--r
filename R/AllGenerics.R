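#' @include AllClasses.R
NULL

#' Accessors for k-mer tables and hapmer sets
#'
#' @param x a [KmerTable-class] or [HapmerSet-class].
#' @return `kmers()` the canonical k-mer strings; `kmerCounts()` their counts;
#'   `kmerK()` the k-mer size; `meanDepth()` the mean count over distinct
#'   k-mers; `nDistinct()` the number of distinct k-mers.
#' @name kmer-accessors
#' @aliases kmers kmerCounts kmerK meanDepth nDistinct
NULL

#' @rdname kmer-accessors
#' @export
setGeneric("kmers", function(x) standardGeneric("kmers"))
#' @rdname kmer-accessors
#' @export
setGeneric("kmerCounts", function(x) standardGeneric("kmerCounts"))
#' @rdname kmer-accessors
#' @export
setGeneric("kmerK", function(x) standardGeneric("kmerK"))
#' @rdname kmer-accessors
#' @export
setGeneric("meanDepth", function(x) standardGeneric("meanDepth"))
#' @rdname kmer-accessors
#' @export
setGeneric("nDistinct", function(x) standardGeneric("nDistinct"))

#' @rdname kmer-accessors
setMethod("kmers", "KmerTable", function(x) x@kmer)
#' @rdname kmer-accessors
setMethod("kmerCounts", "KmerTable", function(x) {
  stats::setNames(x@count, x@kmer)
})
#' @rdname kmer-accessors
setMethod("kmerK", "KmerTable", function(x) x@k)
#' @rdname kmer-accessors
setMethod("meanDepth", "KmerTable", function(x) {
  if (!length(x@count)) return(NA_real_)
  mean(x@count)
})
#' @rdname kmer-accessors
setMethod("nDistinct", "KmerTable", function(x) length(x@kmer))

#' @rdname kmer-accessors
setMethod("kmers", "HapmerSet", function(x) x@kmer)
#' @rdname kmer-accessors
setMethod("kmerK", "HapmerSet", function(x) x@k)

setMethod("show", "KmerTable", function(object) {
  cat("KmerTable: k =", object@k, "|", length(object@kmer),
      "distinct canonical k-mers | mean depth",
      round(meanDepth(object), 2), "\n")
})

setMethod("show", "HapmerSet", function(object) {
  cat("HapmerSet (", object@parent, "): k = ", object@k, ", ",
      length(object@kmer), " hapmers, child depth bounds (",
      object@dmin, ", ", object@dmax, ")\n", sep = "")
})

setMethod("show", "QVReport", function(object) {
  cat("QVReport: genome-wide QV", round(object@qv, 2),
      sprintf("(error %.3g; %d/%d assembly k-mers absent from reads)\n",
              object@errorRate, as.integer(object@absent),
              as.integer(object@total)))
  if (nrow(object@perSeq) > 1L) {
    cat("  per-sequence QV range:",
        paste(round(range(object@perSeq$qv), 2), collapse = " - "), "\n")
  }
})

## ---------------------------------------------------------------------------
## synthetic genome accessors
## ---------------------------------------------------------------------------

#' Accessors for synthetic genomes
#'
#' @param x a [SyntheticGenome-class].
#' @return `chromSeqs()` the chromosome `DNAStringSet`; `truth()` the planted
#'   feature `GRanges`.
#' @name genome-accessors
#' @aliases chromSeqs truth
NULL

#' @rdname genome-accessors
#' @export
setGeneric("chromSeqs", function(x) standardGeneric("chromSeqs"))
#' @rdname genome-accessors
#' @export
setGeneric("truth", function(x) standardGeneric("truth"))

#' @rdname genome-accessors
setMethod("chromSeqs", "SyntheticGenome", function(x) x@seqs)
#' @rdname genome-accessors
setMethod("truth", "SyntheticGenome", function(x) x@truth)

setMethod("show", "SyntheticGenome", function(object) {
  cat("SyntheticGenome:", length(object@seqs), "chromosomes,",
      sum(Biostrings::width(object@seqs)), "bp;",
      length(object@truth), "truth features (",
      paste(names(table(object@truth$label)), collapse = "/"), ")\n")
})

setMethod("show", "TrioHaplotypes", function(object) {
  cat("TrioHaplotypes: het rate", object@hetRate, "|",
      nrow(object@variants), "planted SNVs | child =",
      paste0("paternal hap", object@choice[1L], " + maternal hap",
             object@choice[2L]), "\n")
})

## ---------------------------------------------------------------------------
## genotype matrix accessors
## ---------------------------------------------------------------------------

#' Accessors for genotype matrices
#'
#' @param x a [GenotypeMatrix-class].
#' @return `genotypes()` the sites-by-samples dosage matrix (0/1/2, NA
#'   missing); `populations()` the per-sample population factor;
#'   `siteMAF()` per-site minor allele frequency over non-missing genotypes;
#'   `siteMissingness()` per-site missing fraction.
#' @name genotype-accessors
#' @aliases genotypes populations siteMAF siteMissingness
NULL

#' @rdname genotype-accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname genotype-accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))
#' @rdname genotype-accessors
#' @export
setGeneric("siteMAF", function(x) standardGeneric("siteMAF"))
#' @rdname genotype-accessors
#' @export
setGeneric("siteMissingness", function(x) standardGeneric("siteMissingness"))

#' @rdname genotype-accessors
setMethod("genotypes", "GenotypeMatrix", function(x) {
  SummarizedExperiment::assay(x, "GT")
})
#' @rdname genotype-accessors
setMethod("populations", "GenotypeMatrix", function(x) {
  factor(SummarizedExperiment::colData(x)$population)
})
#' @rdname genotype-accessors
setMethod("siteMAF", "GenotypeMatrix", function(x) {
  g <- genotypes(x)
  n <- 2L * rowSums(!is.na(g))
  p <- rowSums(g, na.rm = TRUE) / pmax(n, 1L)
  ifelse(n == 0L, NA_real_, pmin(p, 1 - p))
})
#' @rdname genotype-accessors
setMethod("siteMissingness", "GenotypeMatrix", function(x) {
  g <- genotypes(x)
  rowMeans(is.na(g))
})

#' Construct a GenotypeMatrix
#'
#' @param geno integer matrix sites x samples, dosages 0/1/2 (NA = missing).
#' @param ranges `GRanges` of site positions (width-1).
#' @param population character/factor of per-sample population labels.
#' @param alleles optional data.frame with `ref`/`alt` columns (stored in
#'   `rowData`); sites default to biallelic A/T placeholders.
#' @return a [GenotypeMatrix-class].
#' @export
GenotypeMatrix <- function(geno, ranges, population, alleles = NULL) {
  stopifnot(nrow(geno) == length(ranges), ncol(geno) == length(population))
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("s%03d", seq_len(ncol(geno)))
  if (is.null(alleles))
    alleles <- data.frame(ref = rep("A", nrow(geno)), alt = rep("T", nrow(geno)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(GT = geno),
    rowRanges = ranges,
    colData = S4Vectors::DataFrame(population = as.character(population),
                                   row.names = colnames(geno)))
  SummarizedExperiment::rowData(se) <- S4Vectors::DataFrame(alleles)
  methods::new("GenotypeMatrix", se)
}
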