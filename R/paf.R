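## PAF alignment records and thin minimap2/samtools wrappers.
##
## Alignments throughout the toolkit follow PAF semantics: 0-based half-open
## coordinates on query and target, number of matching bases, alignment block
## length and mapping quality (0-60).

#' Read a PAF alignment file
#'
#' @param path PAF file path.
#' @return a data.frame with columns `qname`, `qlen`, `qstart`, `qend`,
#'   `strand`, `tname`, `tlen`, `tstart`, `tend`, `nmatch`, `alen`, `mapq`
#'   and `tags` (raw tag string, possibly empty).
#' @export
readPaf <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(emptyPaf())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  core <- t(vapply(parts, function(p) p[1:12], character(12L)))
  tags <- vapply(parts, function(p)
    if (length(p) > 12L) paste(p[-(1:12)], collapse = "\t") else "", character(1L))
  df <- data.frame(
    qname = core[, 1L], qlen = as.integer(core[, 2L]),
    qstart = as.integer(core[, 3L]), qend = as.integer(core[, 4L]),
    strand = core[, 5L], tname = core[, 6L], tlen = as.integer(core[, 7L]),
    tstart = as.integer(core[, 8L]), tend = as.integer(core[, 9L]),
    nmatch = as.integer(core[, 10L]), alen = as.integer(core[, 11L]),
    mapq = as.integer(core[, 12L]), tags = tags, row.names = NULL)
  df
}

#' @rdname readPaf
#' @export
emptyPaf <- function() {
  data.frame(qname = character(0), qlen = integer(0), qstart = integer(0),
             qend = integer(0), strand = character(0), tname = character(0),
             tlen = integer(0), tstart = integer(0), tend = integer(0),
             nmatch = integer(0), alen = integer(0), mapq = integer(0),
             tags = character(0))
}

#' Gap-compressed identity of PAF records
#' @param paf a PAF data.frame.
#' @return numeric identity in `[0, 1]` (`nmatch / alen`).
#' @export
pafIdentity <- function(paf) ifelse(paf$alen > 0, paf$nmatch / paf$alen, 0)

.asFastaFile <- function(x, dir, base) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) return(x)
  if (methods::is(x, "SyntheticGenome")) x <- chromSeqs(x)
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  path <- file.path(dir, paste0(base, ".fa"))
  Biostrings::writeXStringSet(x, path)
  path
}

.haveTool <- function(tool) nzchar(Sys.which(tool))

#' Align sequences with minimap2 and return PAF records
#'
#' Thin wrapper over the minimap2 executable (which must be on `PATH`).
#' Used for reads-vs-assembly and assembly-vs-assembly alignment; the
#' toolkit's own logic consumes only the returned PAF records, so any PAF
#' produced elsewhere works too.
#'
#' @param query,target `DNAStringSet`, [SyntheticGenome-class], character
#'   sequences, or existing FASTA paths.
#' @param preset minimap2 preset (`map-ont`, `map-hifi`, `asm5`, `ava-ont`, ...).
#' @param args extra command-line arguments.
#' @return a PAF data.frame (see [readPaf()]).
#' @export
minimap2Align <- function(query, target, preset = "map-ont",
                          args = c("--secondary=no", "-c")) {
  if (!.haveTool("minimap2")) stop("minimap2 not found on PATH")
  dir <- tempfile("mm2_"); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  qf <- .asFastaFile(query, dir, "query")
  tf <- .asFastaFile(target, dir, "target")
  out <- file.path(dir, "aln.paf")
  status <- system2("minimap2", c("-x", preset, args, "-o", out, tf, qf),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("minimap2 failed (status ", status, ")")
  readPaf(out)
}

#' All-vs-all read overlaps with minimap2
#'
#' @param reads `DNAStringSet` of reads.
#' @param preset overlap preset (default `ava-ont`).
#' @return a PAF data.frame of pairwise overlaps (self-hits removed).
#' @export
minimap2Ava <- function(reads, preset = "ava-ont") {
  paf <- minimap2Align(reads, reads, preset = preset, args = character(0))
  paf[paf$qname != paf$tname, , drop = FALSE]
}

#' Map reads and return a sorted, indexed BAM
#'
#' Runs minimap2 with SAM output and converts/sorts/indexes through
#' [Rsamtools::asBam()]. Needed by the pileup-based polishing steps.
#'
#' @param reads `DNAStringSet` or FASTA/FASTQ path.
#' @param ref reference sequences or FASTA path.
#' @param preset minimap2 preset.
#' @param dest destination path stem (default tempfile).
#' @return path of the sorted BAM file.
#' @export
mapReadsBam <- function(reads, ref, preset = "map-hifi", dest = tempfile("aln_")) {
  if (!.haveTool("minimap2")) stop("minimap2 not found on PATH")
  dir <- tempfile("mm2bam_"); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  qf <- .asFastaFile(reads, dir, "reads")
  tf <- .asFastaFile(ref, dir, "ref")
  sam <- file.path(dir, "aln.sam")
  status <- system2("minimap2",
                    c("-a", "-x", preset, "--secondary=no", "-o", sam, tf, qf),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("minimap2 failed (status ", status, ")")
  Rsamtools::asBam(sam, dest, overwrite = TRUE, indexDestination = TRUE)
}

#' Convert PAF target intervals to GRanges
#' @param paf a PAF data.frame.
#' @return `GRanges` on the target coordinate system with the PAF fields as
#'   metadata columns.
#' @export
pafTargetRanges <- function(paf) {
  gr <- GenomicRanges::GRanges(
    paf$tname, IRanges::IRanges(paf$tstart + 1L, pmax(paf$tend, paf$tstart + 1L)),
    strand = ifelse(paf$strand == "-", "-", "+"))
  S4Vectors::mcols(gr) <- cbind(S4Vectors::mcols(gr), S4Vectors::DataFrame(
    qname = paf$qname, qlen = paf$qlen, qstart = paf$qstart, qend = paf$qend,
    nmatch = paf$nmatch, alen = paf$alen, mapq = paf$mapq))
  gr
}
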