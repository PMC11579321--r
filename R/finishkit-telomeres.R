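## Telomere detection and chromosome-end patching.

.motifRuns <- function(seq, motif, maxInterrupt = 6L) {
  m <- gregexpr(motif, seq, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) return(NULL)
  pos <- as.integer(m)
  w <- nchar(motif)
  ## tandem matches are w apart; allow one short interruption before a run
  ## is considered broken
  gapTo <- c(Inf, pos[-1L] - (pos[-length(pos)] + w))
  runId <- cumsum(gapTo > maxInterrupt)
  do.call(rbind, lapply(split(pos, runId), function(p) {
    data.frame(start = p[1L], end = p[length(p)] + w - 1L, copies = length(p))
  }))
}

#' Detect telomeric arrays at chromosome ends
#'
#' Scans `endScan` bp at each end of every sequence for tandem runs of the
#' telomeric 6-mer on either strand (`TTAGGG` / `CCCTAA`; vertebrate
#' telomerase motif and its reverse complement - both are searched at both
#' ends and the observed motif is recorded). A call requires strictly more
#' than `minCopies` tandem copies.
#'
#' @param assembly `DNAStringSet`/[SyntheticGenome-class]/character.
#' @param minCopies copy-count threshold (call requires copies > minCopies).
#' @param endScan bp scanned at each end.
#' @param motif canonical motif (default `TTAGGG`).
#' @param maxInterrupt bp of interruption tolerated inside an array.
#' @return data.frame of telomere calls: `chrom`, `end` (`5p`/`3p`), `motif`,
#'   `copies`, `start`, `stop` (1-based array interval), `length`,
#'   `distToEnd`.
#' @export
detectTelomeres <- function(assembly, minCopies = 10L, endScan = 10000L,
                            motif = "TTAGGG", maxInterrupt = 6L) {
  seqs <- .asCharSeqs(assembly)
  motifs <- unique(c(motif, .revcomp(motif)))
  calls <- list()
  for (chr in names(seqs)) {
    L <- nchar(seqs[[chr]])
    scan5 <- substr(seqs[[chr]], 1L, min(endScan, L))
    scan3 <- substr(seqs[[chr]], max(1L, L - endScan + 1L), L)
    off3 <- max(1L, L - endScan + 1L) - 1L
    for (m in motifs) {
      r5 <- .motifRuns(scan5, m, maxInterrupt)
      if (!is.null(r5)) {
        r5 <- r5[r5$copies > minCopies, , drop = FALSE]
        for (i in seq_len(nrow(r5)))
          calls[[length(calls) + 1L]] <- data.frame(
            chrom = chr, end = "5p", motif = m, copies = r5$copies[i],
            start = r5$start[i], stop = r5$end[i],
            length = r5$end[i] - r5$start[i] + 1L, distToEnd = r5$start[i] - 1L)
      }
      r3 <- .motifRuns(scan3, m, maxInterrupt)
      if (!is.null(r3)) {
        r3 <- r3[r3$copies > minCopies, , drop = FALSE]
        for (i in seq_len(nrow(r3)))
          calls[[length(calls) + 1L]] <- data.frame(
            chrom = chr, end = "3p", motif = m, copies = r3$copies[i],
            start = off3 + r3$start[i], stop = off3 + r3$end[i],
            length = r3$end[i] - r3$start[i] + 1L,
            distToEnd = L - (off3 + r3$end[i]))
      }
    }
  }
  if (!length(calls))
    return(data.frame(chrom = character(0), end = character(0),
                      motif = character(0), copies = integer(0),
                      start = integer(0), stop = integer(0),
                      length = integer(0), distToEnd = integer(0)))
  df <- do.call(rbind, calls)
  ## an array is assigned to its nearer end (short sequences fall inside
  ## both end scans)
  lens <- nchar(seqs)[df$chrom]
  dist5 <- df$start - 1L
  dist3 <- lens - df$stop
  df <- df[(df$end == "5p" & dist5 <= dist3) |
           (df$end == "3p" & dist3 <= dist5), , drop = FALSE]
  ## one call per (chrom, end): keep the strongest array
  df <- df[order(df$chrom, df$end, -df$copies), , drop = FALSE]
  df <- df[!duplicated(df[, c("chrom", "end")]), , drop = FALSE]
  df <- df[order(df$chrom, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## Estimate the offset mapping contig coordinates onto a window by exact
## probe matching; returns the modal offset supported by >= 2 probes, else NA.
.probeOffset <- function(contig, window, probeLen = 500L, nProbes = 8L,
                         maxMismatch = 5L) {
  cl <- nchar(contig)
  if (cl < probeLen) return(NA_integer_)
  starts <- unique(pmax(1L, round(seq(1L, cl - probeLen + 1L,
                                      length.out = nProbes))))
  offs <- integer(0)
  subj <- Biostrings::DNAString(window)
  for (s in starts) {
    p <- substr(contig, s, s + probeLen - 1L)
    if (grepl("N", p, fixed = TRUE)) next
    hits <- Biostrings::matchPattern(p, subj, max.mismatch = maxMismatch)
    if (length(hits) == 1L)
      offs <- c(offs, Biostrings::start(hits)[1L] - s)
  }
  if (length(offs) < 2L) return(NA_integer_)
  tab <- sort(table(offs), decreasing = TRUE)
  if (tab[1L] < 2L) return(NA_integer_)
  as.integer(names(tab)[1L])
}

.substrIdentity <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  if (n == 0L) return(0)
  sum(ra[seq_len(n)] == rb[seq_len(n)]) / n
}

#' Patch chromosome ends with telomere-bearing contigs
#'
#' A contig carrying a telomeric array is placed onto a chromosome end when
#' it overlaps the terminal window by at least `minOverlap` bp at
#' `>= minIdentity` identity and extends outward; the end is then replaced
#' outward from the overlap, so the patched chromosome terminates in the
#' telomere motif. Contigs whose best placement is interior, or that place
#' ambiguously on several ends, are left unplaced and reported.
#'
#' @param assembly `DNAStringSet`/character chromosomes.
#' @param contigs named `DNAStringSet` of telomere-bearing contigs.
#' @param endWindow terminal window searched (default 1 Mb).
#' @param minOverlap minimum contig/end overlap (default 10 kb).
#' @param minIdentity minimum overlap identity (default 0.99).
#' @param minCopies telomere copies required on the contig's outward end.
#' @return a list: `assembly` (patched `DNAStringSet`) and `report`
#'   (data.frame: `contig`, `chrom`, `end`, `action`, `extension`).
#' @export
patchChromosomeEnds <- function(assembly, contigs, endWindow = 1000000L,
                                minOverlap = 10000L, minIdentity = 0.99,
                                minCopies = 10L) {
  seqs <- .asCharSeqs(assembly)
  ctg <- .asCharSeqs(contigs)
  report <- list()
  note <- function(contig, chrom, end, action, ext = 0L) {
    report[[length(report) + 1L]] <<- data.frame(
      contig = contig, chrom = chrom, end = end, action = action,
      extension = ext)
  }
  for (cn in names(ctg)) {
    tel <- detectTelomeres(stats::setNames(ctg[cn], cn), minCopies = minCopies)
    if (!nrow(tel)) { note(cn, NA, NA, "no_telomere"); next }
    placements <- list()
    for (chr in names(seqs)) {
      L <- nchar(seqs[[chr]])
      for (endSide in c("5p", "3p")) {
        win <- if (endSide == "5p") substr(seqs[[chr]], 1L, min(endWindow, L))
               else substr(seqs[[chr]], max(1L, L - endWindow + 1L), L)
        for (ori in c("+", "-")) {
          cs <- if (ori == "+") ctg[[cn]] else .revcomp(ctg[[cn]])
          off <- .probeOffset(cs, win)
          if (is.na(off)) next
          cl <- nchar(cs); wl <- nchar(win)
          ovS <- max(1L, 1L + off); ovE <- min(wl, cl + off)
          ovLen <- ovE - ovS + 1L
          if (ovLen < minOverlap) next
          ident <- .substrIdentity(substr(cs, ovS - off, ovE - off),
                                   substr(win, ovS, ovE))
          if (ident < minIdentity) next
          ## outward extension: contig must reach past the chromosome end
          outward <- if (endSide == "5p") off <= 0L else
            (off + cl) >= wl
          if (!outward) next
          placements[[length(placements) + 1L]] <- list(
            chrom = chr, end = endSide, ori = ori, off = off,
            ident = ident, ovLen = ovLen)
        }
      }
    }
    if (!length(placements)) { note(cn, NA, NA, "unplaced"); next }
    ends <- unique(vapply(placements, function(p) paste(p$chrom, p$end),
                          character(1L)))
    if (length(ends) > 1L) { note(cn, NA, NA, "ambiguous"); next }
    p <- placements[[which.max(vapply(placements, `[[`, numeric(1L), "ident"))]]
    cs <- if (p$ori == "+") ctg[[cn]] else .revcomp(ctg[[cn]])
    chr <- p$chrom; L <- nchar(seqs[[chr]]); cl <- nchar(cs)
    ## the contig's telomere must face outward
    telOut <- detectTelomeres(stats::setNames(cs, cn), minCopies = minCopies)
    if (!nrow(telOut) || !any(telOut$end == p$end)) {
      note(cn, chr, p$end, "telomere_faces_inward"); next
    }
    if (p$end == "5p") {
      cut <- cl + p$off                 # chromosome coord of contig end
      newLen <- cl + (L - cut)
      seqs[[chr]] <- paste0(cs, substr(seqs[[chr]], cut + 1L, L))
      note(cn, chr, "5p", "patched", newLen - L)
    } else {
      wOff <- max(1L, L - endWindow + 1L) - 1L
      start <- wOff + p$off             # chromosome coord before contig start
      newLen <- start + cl
      seqs[[chr]] <- paste0(substr(seqs[[chr]], 1L, start), cs)
      note(cn, chr, "3p", "patched", newLen - L)
    }
  }
  list(assembly = Biostrings::DNAStringSet(seqs),
       report = if (length(report)) do.call(rbind, report) else
         data.frame(contig = character(0), chrom = character(0),
                    end = character(0), action = character(0),
                    extension = integer(0)))
}
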