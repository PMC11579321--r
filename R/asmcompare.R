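## Assembly-to-assembly comparison: synteny chaining, inversion calls, and
## previously-unresolved-region (PUR/NAR) detection.

#' Chain alignments into synteny blocks and call inversions
#'
#' Alignments sharing query/target chromosome and orientation are chained
#' when consecutive records are within `maxGap` on both axes and on the
#' alignment diagonal; reverse-orientation blocks of at least `minBlock` are
#' reported as inversions. Unaligned insertions larger than `maxGap` split a
#' block in two.
#'
#' @param paf assembly-vs-assembly PAF data.frame.
#' @param minBlock minimum block span on the target (default 100 kb).
#' @param maxGap maximum chaining gap (default 50 kb).
#' @return a list: `blocks` and `inversions`, data.frames with `qname`,
#'   `tname`, `strand`, `qstart`, `qend`, `tstart`, `tend` (0-based
#'   half-open), `n` (chained records) and `identity` (mean).
#' @export
chainSynteny <- function(paf, minBlock = 100000L, maxGap = 50000L) {
  if (!nrow(paf)) return(list(blocks = NULL, inversions = NULL))
  paf <- paf[order(paf$qname, paf$tname, paf$strand, paf$tstart), , drop = FALSE]
  key <- paste(paf$qname, paf$tname, paf$strand)
  blocks <- list()
  for (k in unique(key)) {
    a <- paf[key == k, , drop = FALSE]
    chain <- 1L
    id <- integer(nrow(a)); id[1L] <- chain
    for (i in seq_len(nrow(a))[-1L]) {
      tgap <- a$tstart[i] - a$tend[i - 1L]
      qgap <- if (a$strand[i] == "+") a$qstart[i] - a$qend[i - 1L]
              else a$qstart[i - 1L] - a$qend[i]
      ok <- tgap <= maxGap && tgap > -maxGap && qgap <= maxGap && qgap > -maxGap
      if (!ok) chain <- chain + 1L
      id[i] <- chain
    }
    for (cid in unique(id)) {
      b <- a[id == cid, , drop = FALSE]
      blocks[[length(blocks) + 1L]] <- data.frame(
        qname = b$qname[1L], tname = b$tname[1L], strand = b$strand[1L],
        qstart = min(b$qstart), qend = max(b$qend),
        tstart = min(b$tstart), tend = max(b$tend),
        n = nrow(b), identity = mean(pafIdentity(b)))
    }
  }
  blocks <- do.call(rbind, blocks)
  blocks <- blocks[blocks$tend - blocks$tstart >= minBlock, , drop = FALSE]
  blocks <- blocks[order(blocks$tname, blocks$tstart), , drop = FALSE]
  rownames(blocks) <- NULL
  inv <- blocks[blocks$strand == "-", , drop = FALSE]
  rownames(inv) <- NULL
  list(blocks = blocks, inversions = inv)
}

## Best-reciprocal one-to-one filtering: alignments are taken by decreasing
## matches; a record is kept when it overlaps previously kept records by
## < maxOvFrac on both its query and its target interval.
.filterOneToOne <- function(paf, minAln = 10000L, maxOvFrac = 0.5) {
  paf <- paf[paf$alen >= minAln, , drop = FALSE]
  if (!nrow(paf)) return(paf)
  paf <- paf[order(-paf$nmatch), , drop = FALSE]
  keptQ <- GenomicRanges::GRanges(); keptT <- GenomicRanges::GRanges()
  keep <- logical(nrow(paf))
  for (i in seq_len(nrow(paf))) {
    q <- GenomicRanges::GRanges(paf$qname[i],
                                IRanges::IRanges(paf$qstart[i] + 1L, paf$qend[i]))
    t <- GenomicRanges::GRanges(paf$tname[i],
                                IRanges::IRanges(paf$tstart[i] + 1L, paf$tend[i]))
    ovQ <- sum(IRanges::width(GenomicRanges::intersect(
      q, keptQ, ignore.strand = TRUE)))
    ovT <- sum(IRanges::width(GenomicRanges::intersect(
      t, keptT, ignore.strand = TRUE)))
    if (ovQ < maxOvFrac * IRanges::width(q) &&
        ovT < maxOvFrac * IRanges::width(t)) {
      keep[i] <- TRUE
      suppressWarnings({
        keptQ <- c(keptQ, q); keptT <- c(keptT, t)
      })
    }
  }
  paf[keep, , drop = FALSE]
}

#' Detect previously unresolved regions (PURs) and newly assembled regions
#'
#' PUR = bases of the new assembly not covered by any filtered one-to-one
#' alignment to the old assembly's chromosomes (merged; segments >=
#' `minSegment`). NAR = the subset of PUR additionally uncovered by
#' alignments to the old assembly's unplaced contigs (NAR is always contained
#' in PUR).
#'
#' @param pafChrom PAF of the new assembly (query) aligned to the old
#'   chromosomes.
#' @param newSeqlens named lengths of the new assembly sequences.
#' @param pafUnplaced optional PAF of the new assembly aligned to the old
#'   unplaced contigs.
#' @param minAln minimum alignment length used for coverage (default 10 kb).
#' @param minSegment minimum reported segment (default 5 kb; guards against
#'   crediting alignment jitter as PUR).
#' @return a list of `GRanges`: `pur` and `nar` (on new-assembly
#'   coordinates, with a `basis` column).
#' @export
detectPURs <- function(pafChrom, newSeqlens, pafUnplaced = NULL,
                       minAln = 10000L, minSegment = 5000L) {
  filt <- .filterOneToOne(pafChrom, minAln = minAln)
  qcov <- if (nrow(filt)) GenomicRanges::reduce(GenomicRanges::GRanges(
    filt$qname, IRanges::IRanges(filt$qstart + 1L, filt$qend))) else
    GenomicRanges::GRanges()
  genome <- GenomicRanges::GRanges(names(newSeqlens),
                                   IRanges::IRanges(1L, unname(newSeqlens)))
  GenomeInfoDb::seqlevels(genome) <- names(newSeqlens)
  GenomeInfoDb::seqlengths(genome) <- unname(newSeqlens)
  GenomeInfoDb::seqlevels(qcov) <- names(newSeqlens)
  pur <- GenomicRanges::setdiff(genome, qcov, ignore.strand = TRUE)
  pur <- pur[IRanges::width(pur) >= minSegment]
  pur$basis <- rep("uncovered-by-chromosomes", length(pur))
  nar <- pur
  if (!is.null(pafUnplaced) && nrow(pafUnplaced)) {
    up <- pafUnplaced[pafUnplaced$alen >= minAln, , drop = FALSE]
    ucov <- if (nrow(up)) GenomicRanges::reduce(GenomicRanges::GRanges(
      up$qname, IRanges::IRanges(up$qstart + 1L, up$qend))) else
      GenomicRanges::GRanges()
    GenomeInfoDb::seqlevels(ucov) <- names(newSeqlens)
    nar <- GenomicRanges::setdiff(pur, ucov, ignore.strand = TRUE)
    nar <- nar[IRanges::width(nar) >= minSegment]
  }
  nar$basis <- rep("uncovered-by-all", length(nar))
  list(pur = pur, nar = nar)
}
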