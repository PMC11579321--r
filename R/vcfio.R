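## Minimal VCF interchange for genotype panels (GT-only), plus a population
## map. Writing emits standard VCFv4.2 text; reading goes through vcfR.

#' Write a genotype matrix as a minimal GT-only VCF
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output VCF path (uncompressed).
#' @param popmapPath optional path for a two-column sample/population TSV.
#' @return invisibly, `path`.
#' @export
writeGenotypeVcf <- function(gm, path, popmapPath = NULL) {
  rr <- SummarizedExperiment::rowRanges(gm)
  rd <- SummarizedExperiment::rowData(gm)
  g <- genotypes(gm)
  gtStr <- matrix("./.", nrow(g), ncol(g))
  gtStr[!is.na(g) & g == 0L] <- "0/0"
  gtStr[!is.na(g) & g == 1L] <- "0/1"
  gtStr[!is.na(g) & g == 2L] <- "1/1"
  seqlens <- GenomeInfoDb::seqlengths(rr)
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", names(seqlens),
                      unname(seqlens)),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(g)), collapse = "\t"))
  body <- paste(as.character(GenomeInfoDb::seqnames(rr)),
                GenomicRanges::start(rr),
                sprintf("site%d", seq_len(nrow(g))),
                if ("ref" %in% names(rd)) rd$ref else "A",
                if ("alt" %in% names(rd)) rd$alt else "T",
                ".", "PASS", ".", "GT",
                apply(gtStr, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  if (!is.null(popmapPath))
    utils::write.table(
      data.frame(sample = colnames(g),
                 population = as.character(populations(gm))),
      popmapPath, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  invisible(path)
}

#' Read a GT-only VCF (plus population map) into a GenotypeMatrix
#'
#' @param path VCF path.
#' @param popmap either a data.frame (`sample`, `population`), the path of a
#'   two-column TSV, or `NULL` (all samples labelled `pop1`).
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypeVcf <- function(path, popmap = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt),
                   dimnames = dimnames(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dosage[clean %in% c("0/0")] <- 0L
  dosage[clean %in% c("0/1", "1/0")] <- 1L
  dosage[clean %in% c("1/1")] <- 2L
  fix <- vcfR::getFIX(v)
  gr <- GenomicRanges::GRanges(fix[, "CHROM"],
                               IRanges::IRanges(as.integer(fix[, "POS"]),
                                                as.integer(fix[, "POS"])))
  if (is.character(popmap))
    popmap <- utils::read.table(popmap, sep = "\t",
                                col.names = c("sample", "population"),
                                colClasses = "character")
  pops <- if (is.null(popmap)) rep("pop1", ncol(dosage)) else
    popmap$population[match(colnames(dosage), popmap$sample)]
  GenotypeMatrix(dosage, gr, pops,
                 alleles = data.frame(ref = unname(fix[, "REF"]),
                                      alt = unname(fix[, "ALT"])))
}
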