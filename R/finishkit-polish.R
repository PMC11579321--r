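## Polish-region classification and pileup consensus polishing.

#' Classify chromosome windows into low- and high-quality segments
#'
#' A window is low-quality when any of the classic triggers holds: median
#' mapping quality of overlapping reads <= `maxMapq`, presence of reads
#' clipped at both ends, or fewer than `minReads` covering reads. Adjacent
#' windows of the same label are merged; the segments partition each
#' chromosome.
#'
#' @param paf PAF data.frame of (HiFi) reads vs the assembly.
#' @param seqlens named chromosome lengths.
#' @param window window size in bp (default 1 kb).
#' @param minReads coverage trigger (default < 3 reads).
#' @param maxMapq mapping-quality trigger (default <= 1).
#' @param clipTol bases of terminal softclip tolerated before a read end
#'   counts as clipped.
#' @return `GRanges` segments with `label` (`low`/`high`) and `reason`
#'   metadata columns.
#' @export
classifyPolishRegions <- function(paf, seqlens, window = 1000L, minReads = 3L,
                                  maxMapq = 1L, clipTol = 100L) {
  wins <- .tileWindows(seqlens, as.integer(window))
  aln <- pafTargetRanges(paf)
  bothClipped <- paf$qstart > clipTol & (paf$qlen - paf$qend) > clipTol
  ov <- GenomicRanges::findOverlaps(wins, aln, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  nReads <- tabulate(qh, nbins = length(wins))
  medMapq <- rep(NA_real_, length(wins))
  if (length(qh)) {
    spl <- split(paf$mapq[sh], qh)
    medMapq[as.integer(names(spl))] <- vapply(spl, stats::median, numeric(1L))
  }
  clip <- rep(FALSE, length(wins))
  if (length(qh)) {
    spl <- split(bothClipped[sh], qh)
    clip[as.integer(names(spl))] <- vapply(spl, any, logical(1L))
  }
  low <- nReads < minReads | (!is.na(medMapq) & medMapq <= maxMapq) | clip
  reason <- rep("", length(wins))
  reason[nReads < minReads] <- "coverage"
  reason[!is.na(medMapq) & medMapq <= maxMapq] <-
    paste0(reason[!is.na(medMapq) & medMapq <= maxMapq], ";mapq")
  reason[clip] <- paste0(reason[clip], ";clipped")
  wins$label <- ifelse(low, "low", "high")
  wins$reason <- sub("^;", "", reason)
  ## merge adjacent same-label windows per chromosome
  out <- list()
  for (chr in GenomeInfoDb::seqlevels(wins)) {
    w <- wins[GenomeInfoDb::seqnames(wins) == chr]
    if (!length(w)) next
    grp <- cumsum(c(TRUE, w$label[-1L] != w$label[-length(w)]))
    for (g in unique(grp)) {
      idx <- which(grp == g)
      seg <- GenomicRanges::GRanges(
        chr, IRanges::IRanges(min(GenomicRanges::start(w[idx])),
                              max(GenomicRanges::end(w[idx]))))
      seg$label <- w$label[idx[1L]]
      seg$reason <- paste(unique(setdiff(unlist(
        strsplit(w$reason[idx], ";")), "")), collapse = ";")
      out[[length(out) + 1L]] <- seg
    }
  }
  res <- suppressWarnings(do.call(c, out))
  GenomeInfoDb::seqlengths(res) <- seqlens[GenomeInfoDb::seqlevels(res)]
  res
}

#' Majority-consensus pileup polishing
#'
#' Substitution-only consensus polish: at every column with read depth
#' >= `minDepth` where the majority base reaches `minFrac` and differs from
#' the assembly base, the assembly base is replaced. Optionally restricted to
#' target regions (e.g. the low-quality segments from
#' [classifyPolishRegions()], mirroring the staged low-quality-first
#' polishing pipeline).
#'
#' @param assembly `DNAStringSet`/character assembly (the BAM's reference).
#' @param bam path to a sorted, indexed BAM (see [mapReadsBam()]).
#' @param minDepth minimum column depth (default 3).
#' @param minFrac minimum majority fraction (default 0.6).
#' @param regions optional `GRanges` restricting where edits may be applied.
#' @return a list: `assembly` (corrected `DNAStringSet`) and `edits`
#'   (data.frame: `chrom`, `pos`, `ref`, `alt`, `depth`, `frac`).
#' @export
pileupPolish <- function(assembly, bam, minDepth = 3L, minFrac = 0.6,
                         regions = NULL) {
  seqs <- .asCharSeqs(assembly)
  pp <- Rsamtools::PileupParam(max_depth = 10000L, min_base_quality = 0L,
                               min_mapq = 0L, distinguish_strands = FALSE,
                               include_deletions = FALSE,
                               include_insertions = FALSE)
  sbp <- if (is.null(regions)) Rsamtools::ScanBamParam() else
    Rsamtools::ScanBamParam(which = GenomicRanges::reduce(regions))
  p <- Rsamtools::pileup(bam, scanBamParam = sbp, pileupParam = pp)
  edits <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      depth = integer(0), frac = numeric(0))
  if (nrow(p)) {
    key <- paste(p$seqnames, p$pos)
    depth <- tapply(p$count, key, sum)
    best <- tapply(seq_len(nrow(p)), key, function(i) i[which.max(p$count[i])])
    bi <- as.integer(best)
    d <- as.integer(depth[names(best)])
    frac <- p$count[bi] / d
    keep <- d >= minDepth & frac >= minFrac
    cand <- data.frame(chrom = as.character(p$seqnames[bi]), pos = p$pos[bi],
                       alt = as.character(p$nucleotide[bi]), depth = d,
                       frac = frac)[keep, , drop = FALSE]
    if (nrow(cand)) {
      cand$ref <- substring(unlist(seqs[cand$chrom]), cand$pos, cand$pos)
      cand <- cand[cand$ref != cand$alt & cand$alt %in% c("A", "C", "G", "T"),
                   , drop = FALSE]
      if (!is.null(regions) && nrow(cand)) {
        gr <- GenomicRanges::GRanges(cand$chrom,
                                     IRanges::IRanges(cand$pos, cand$pos))
        cand <- cand[IRanges::overlapsAny(gr, regions), , drop = FALSE]
      }
      if (nrow(cand)) {
        for (i in seq_len(nrow(cand)))
          substr(seqs[[cand$chrom[i]]], cand$pos[i], cand$pos[i]) <- cand$alt[i]
        edits <- cand[, c("chrom", "pos", "ref", "alt", "depth", "frac")]
        rownames(edits) <- NULL
      }
    }
  }
  list(assembly = Biostrings::DNAStringSet(seqs), edits = edits)
}
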