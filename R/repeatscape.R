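## Satellite monomer discovery, centromere evidence integration, identity
## heatmaps, complexity tracks and segmental duplication detection.

.rotations <- function(s) {
  n <- nchar(s)
  vapply(seq_len(n), function(i)
    paste0(substr(s, i, n), substr(s, 1L, i - 1L)), character(1L))
}

#' Canonical rotation of a tandem repeat monomer
#'
#' Lexicographic minimum over all rotations of the monomer and of its
#' reverse complement, making monomer comparisons rotation- and
#' strand-invariant.
#' @param s monomer string.
#' @return the canonical rotation.
#' @export
canonicalRotation <- function(s) {
  min(c(.rotations(s), .rotations(.revcomp(s))))
}

.rotationIdentity <- function(a, b) {
  ## identity between monomers up to rotation and strand (doubled-string
  ## alignment trick)
  if (abs(nchar(a) - nchar(b)) / max(nchar(a), nchar(b)) > 0.5) return(0)
  best <- 0
  for (cand in c(b, .revcomp(b))) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(cand),
      Biostrings::DNAString(paste0(a, a)), type = "local")
    best <- max(best, 100 * Biostrings::nmatch(aln) / nchar(cand))
  }
  best
}

#' Discover satellite monomers from a k-mer table
#'
#' Greedy circular extension over the k-mer count table: the highest-count
#' unconsumed k-mer seeds a walk that repeatedly appends the most frequent
#' successor base; when the walk returns to its seed the traversed bases form
#' one monomer. Consumed k-mers are removed and the next family is seeded,
#' until counts fall below `minCount`. Near-duplicate units (>= 80% identity
#' up to rotation and strand) are collapsed. Monomers are reported in
#' canonical rotation.
#'
#' @param x a [KmerTable-class] built from candidate centromeric sequence, or
#'   sequences (a table is then built with `k`, counting all k-mers).
#' @param k k-mer size when `x` is a sequence set (the classic satellite
#'   discovery setting uses k = 151 with a count floor of 20).
#' @param minCount minimum seed count (default 20).
#' @param extendMin minimum successor count during extension
#'   (default `max(2, minCount %/% 2)`).
#' @param maxMonomer maximum monomer length (default 5000).
#' @param maxUnits maximum number of units returned.
#' @param collapseIdentity identity above which two units merge.
#' @return data.frame of satellite units: `family`, `monomer` (canonical
#'   rotation), `length`, `support` (seed k-mer count).
#' @export
discoverSatelliteUnits <- function(x, k = 151L, minCount = 20L,
                                   extendMin = max(2L, minCount %/% 2L),
                                   maxMonomer = 5000L, maxUnits = 10L,
                                   collapseIdentity = 80) {
  tab <- if (methods::is(x, "KmerTable")) x else countKmers(x, k)
  if (!length(tab@kmer)) stop("empty k-mer table")
  k <- tab@k
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(tab@kmer)) assign(tab@kmer[i], tab@count[i], envir = env)
  lookup <- function(km) {
    rc <- .revcomp(km)
    key <- if (km <= rc) km else rc
    v <- get0(key, envir = env, ifnotfound = 0L)
    list(key = key, count = v)
  }
  live <- tab@kmer[tab@count >= minCount]
  liveCount <- tab@count[tab@count >= minCount]
  ord <- order(-liveCount, live)
  live <- live[ord]; liveCount <- liveCount[ord]
  consumed <- character(0)
  units <- list()
  bases <- c("A", "C", "G", "T")
  for (si in seq_along(live)) {
    if (length(units) >= maxUnits) break
    seed <- live[si]
    if (seed %in% consumed) next
    if (lookup(seed)$count < minCount) next
    cur <- seed
    walked <- character(0)
    cycle <- NULL
    visitedKeys <- lookup(seed)$key
    for (step in seq_len(maxMonomer)) {
      succ <- paste0(substr(cur, 2L, k), bases)
      cnt <- vapply(succ, function(s) lookup(s)$count, numeric(1L))
      j <- which.max(cnt)  # ties break to A<C<G<T order
      if (cnt[j] < extendMin) break
      cur <- succ[j]
      walked <- c(walked, bases[j])
      visitedKeys <- c(visitedKeys, lookup(cur)$key)
      if (cur == seed || lookup(cur)$key == lookup(seed)$key) {
        cycle <- walked
        break
      }
    }
    consumed <- c(consumed, unique(visitedKeys))
    for (key in unique(visitedKeys))
      if (exists(key, envir = env)) rm(list = key, envir = env)
    if (is.null(cycle)) next
    monomer <- canonicalRotation(paste(cycle, collapse = ""))
    support <- liveCount[si]
    dup <- FALSE
    for (u in units) {
      if (.rotationIdentity(u$monomer, monomer) >= collapseIdentity) {
        dup <- TRUE; break
      }
    }
    if (!dup)
      units[[length(units) + 1L]] <- list(monomer = monomer,
                                          length = nchar(monomer),
                                          support = support)
  }
  if (!length(units))
    return(data.frame(family = character(0), monomer = character(0),
                      length = integer(0), support = integer(0)))
  data.frame(family = sprintf("unit%d", seq_along(units)),
             monomer = vapply(units, `[[`, character(1L), "monomer"),
             length = vapply(units, `[[`, integer(1L), "length"),
             support = vapply(units, `[[`, numeric(1L), "support"))
}

#' Annotate satellite arrays by monomer alignment
#'
#' Monomer occurrences (both strands, substitution tolerance from
#' `minIdentity`) are located genome-wide and maximal runs of consecutive
#' hits are merged into arrays.
#'
#' @param genome sequences to annotate.
#' @param units data.frame from [discoverSatelliteUnits()] (or with columns
#'   `family`, `monomer`).
#' @param minIdentity minimum per-copy identity (default 0.80).
#' @param mergeFactor runs closer than `mergeFactor * monomer length` merge.
#' @return `GRanges` of arrays with `family`, `copies` and `identity`
#'   metadata columns.
#' @export
annotateSatellites <- function(genome, units, minIdentity = 0.80,
                               mergeFactor = 2) {
  if (!nrow(units)) stop("units must be non-empty")
  seqs <- .asCharSeqs(genome)
  out <- list()
  for (ui in seq_len(nrow(units))) {
    mono <- units$monomer[ui]
    len <- nchar(mono)
    maxMM <- floor((1 - minIdentity) * len)
    for (chr in names(seqs)) {
      subj <- Biostrings::DNAString(seqs[[chr]])
      for (pat in unique(c(mono, .revcomp(mono)))) {
        hits <- Biostrings::matchPattern(pat, subj, max.mismatch = maxMM)
        if (!length(hits)) next
        st <- Biostrings::start(hits)
        mm <- Biostrings::neditStartingAt(Biostrings::DNAString(pat), subj,
                                          starting.at = st, with.indels = FALSE)
        grp <- cumsum(c(TRUE, diff(st) > mergeFactor * len))
        for (g in unique(grp)) {
          idx <- which(grp == g)
          if (length(idx) < 2L) next
          out[[length(out) + 1L]] <- data.frame(
            chrom = chr, start = st[idx[1L]], end = st[idx[length(idx)]] + len - 1L,
            family = units$family[ui], copies = length(idx),
            identity = 100 * mean(1 - mm[idx] / len))
        }
      }
    }
  }
  if (!length(out)) return(GenomicRanges::GRanges())
  df <- do.call(rbind, out)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               family = df$family, copies = df$copies,
                               identity = df$identity)
  ## merge overlapping same-family runs (different phases of the same array)
  res <- list()
  for (fam in unique(gr$family)) {
    g <- gr[gr$family == fam]
    r <- GenomicRanges::reduce(g, min.gapwidth = 1L)
    ov <- GenomicRanges::findOverlaps(r, g)
    cp <- vapply(split(g$copies[S4Vectors::subjectHits(ov)],
                       S4Vectors::queryHits(ov)), max, numeric(1L))
    id <- vapply(split(g$identity[S4Vectors::subjectHits(ov)],
                       S4Vectors::queryHits(ov)), max, numeric(1L))
    r$family <- rep(fam, length(r))
    r$copies <- as.integer(unname(cp)); r$identity <- unname(id)
    res[[fam]] <- r
  }
  sort(suppressWarnings(do.call(c, unname(res))), ignore.strand = TRUE)
}

#' Linguistic complexity track
#'
#' Per tiling window, the observed number of distinct substrings divided by
#' the maximum possible, averaged over substring lengths 1..`maxLen`.
#' Satellite arrays depress the value; random sequence approaches 1.
#'
#' @param genome sequences.
#' @param window window size (default 10 kb).
#' @param maxLen largest substring length (default 12).
#' @return `GRanges` of windows with a `complexity` column in (0, 1].
#' @export
complexityTrack <- function(genome, window = 10000L, maxLen = 12L) {
  seqs <- .asCharSeqs(genome)
  seqlens <- stats::setNames(nchar(seqs), names(seqs))
  wins <- .tileWindows(seqlens, as.integer(window))
  cx <- numeric(length(wins))
  for (i in seq_along(wins)) {
    chr <- as.character(GenomeInfoDb::seqnames(wins[i]))
    s <- substr(seqs[[chr]], GenomicRanges::start(wins[i]),
                GenomicRanges::end(wins[i]))
    n <- nchar(s)
    vals <- vapply(seq_len(min(maxLen, n)), function(u) {
      subs <- substring(s, 1:(n - u + 1L), u:n)
      length(unique(subs)) / min(4^u, n - u + 1L)
    }, numeric(1L))
    cx[i] <- mean(vals)
  }
  wins$complexity <- cx
  wins
}

#' Mean read depth per tiling window
#'
#' @param alignments PAF data.frame or `GRanges` of aligned intervals.
#' @param seqlens named chromosome lengths.
#' @param window window size (ChIP enrichment conventionally 5 kb,
#'   methylation coverage 20 kb).
#' @return `GRanges` windows with a `depth` column (mean per-base depth).
#' @export
windowDepthTrack <- function(alignments, seqlens, window = 5000L) {
  gr <- if (methods::is(alignments, "GRanges")) alignments else
    pafTargetRanges(alignments)
  gr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                               IRanges::IRanges(GenomicRanges::start(gr),
                                                GenomicRanges::end(gr)))
  GenomeInfoDb::seqlevels(gr) <- names(seqlens)
  GenomeInfoDb::seqlengths(gr) <- unname(seqlens)
  gr <- GenomicRanges::trim(gr)
  cov <- GenomicRanges::coverage(gr)
  bins <- .tileWindows(seqlens, as.integer(window))
  GenomicRanges::binnedAverage(bins, cov, "depth")
}

#' Call centromeres from combined evidence
#'
#' Windows exceeding per-track thresholds (ChIP depth >= `chipFactor` x
#' genome median; methylation >= `methFactor` x median; satellite density
#' >= `satMin`; complexity <= the genome-wide `complexityQuantile` quantile)
#' are overlaid; merged candidate regions supported by at least two evidence
#' types become calls, at most one per chromosome by default (acrocentric
#' model; the strongest/longest candidate wins).
#'
#' @param tracks named list of `GRanges` window tracks; recognised names are
#'   `chip` (`depth` column), `methylation` (`depth` or `score`),
#'   `satellite` (`density` in 0..1) and `complexity` (`complexity`).
#' @param satAnnotation optional satellite `GRanges` (from
#'   [annotateSatellites()]) used to report the dominant family.
#' @param chipFactor,methFactor,satMin,complexityQuantile thresholds.
#' @param mergeGap candidate windows closer than this merge (default 100 kb).
#' @param minEvidence evidence types required (default 2).
#' @param onePerChrom keep only the best call per chromosome.
#' @return `GRanges` of centromere calls with `evidence`, `nEvidence` and
#'   `dominantFamily` columns.
#' @export
callCentromeres <- function(tracks, satAnnotation = NULL, chipFactor = 2,
                            methFactor = 1.5, satMin = 0.5,
                            complexityQuantile = 0.1, mergeGap = 100000L,
                            minEvidence = 2L, onePerChrom = TRUE) {
  .score <- function(gr) {
    for (nm in c("depth", "score", "density", "complexity"))
      if (nm %in% names(S4Vectors::mcols(gr))) return(S4Vectors::mcols(gr)[[nm]])
    stop("track without a recognised score column")
  }
  passing <- list()
  for (nm in names(tracks)) {
    gr <- tracks[[nm]]
    v <- .score(gr)
    keep <- switch(nm,
      chip = v >= chipFactor * stats::median(v),
      methylation = v >= methFactor * stats::median(v),
      satellite = v >= satMin,
      complexity = v <= stats::quantile(v, complexityQuantile),
      stop("unknown evidence track: ", nm))
    p <- gr[keep]
    S4Vectors::mcols(p) <- NULL
    p$evidence <- rep(nm, length(p))
    passing[[nm]] <- p
  }
  ## a window only seeds a candidate when a *different* evidence type also
  ## passes at an overlapping window (pairwise corroboration keeps isolated
  ## single-track noise out of the merged call)
  corroborated <- lapply(names(passing), function(nm) {
    p <- passing[[nm]]
    if (!length(p)) return(p)
    others <- suppressWarnings(do.call(c, unname(passing[setdiff(
      names(passing), nm)])))
    suppressWarnings(p[IRanges::overlapsAny(p, others, ignore.strand = TRUE)])
  })
  allPass <- suppressWarnings(do.call(c, unname(corroborated)))
  if (!length(allPass)) return(GenomicRanges::GRanges())
  cand <- GenomicRanges::reduce(allPass, min.gapwidth = mergeGap,
                                ignore.strand = TRUE)
  ev <- vapply(seq_along(cand), function(i) {
    hits <- vapply(passing, function(p)
      IRanges::overlapsAny(cand[i], p), logical(1L))
    paste(names(passing)[hits], collapse = ",")
  }, character(1L))
  nEv <- lengths(strsplit(ev, ","))
  cand$evidence <- ev
  cand$nEvidence <- nEv
  cand <- cand[nEv >= minEvidence]
  if (onePerChrom && length(cand)) {
    keep <- unlist(lapply(split(seq_along(cand),
                                as.character(GenomeInfoDb::seqnames(cand))),
                          function(idx) {
      idx[order(-cand$nEvidence[idx], -IRanges::width(cand)[idx])][1L]
    }))
    cand <- sort(cand[keep], ignore.strand = TRUE)
  }
  fam <- rep(NA_character_, length(cand))
  if (!is.null(satAnnotation) && length(cand)) {
    for (i in seq_along(cand)) {
      ov <- satAnnotation[IRanges::overlapsAny(satAnnotation, cand[i])]
      if (length(ov)) {
        byFam <- tapply(IRanges::width(ov), ov$family, sum)
        fam[i] <- names(byFam)[which.max(byFam)]
      }
    }
  }
  cand$dominantFamily <- fam
  cand
}

#' Satellite density track from an annotation
#'
#' @param satAnnotation `GRanges` from [annotateSatellites()].
#' @param seqlens named chromosome lengths.
#' @param window window size (default 10 kb).
#' @return `GRanges` windows with a `density` column in `[0, 1]`.
#' @export
satelliteDensityTrack <- function(satAnnotation, seqlens, window = 10000L) {
  bins <- .tileWindows(seqlens, as.integer(window))
  gr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(satAnnotation),
                               IRanges::IRanges(
                                 GenomicRanges::start(satAnnotation),
                                 GenomicRanges::end(satAnnotation)))
  GenomeInfoDb::seqlevels(gr) <- names(seqlens)
  GenomeInfoDb::seqlengths(gr) <- unname(seqlens)
  cov <- GenomicRanges::coverage(GenomicRanges::reduce(gr))
  res <- GenomicRanges::binnedAverage(bins, cov, "density")
  res$density <- pmin(res$density, 1)
  res
}

#' Pairwise window identity matrix
#'
#' Percent identity (matches over alignment columns) of the global
#' alignment - best of both strands - between every pair of tiling windows of
#' one sequence; the visual basis of satellite-array identity heatmaps.
#' Whole windows are aligned end to end, so unrelated windows score at the
#' random-sequence baseline rather than on short chance matches. Diagonal is
#' 100 by definition.
#'
#' @param seq a single sequence (character or `DNAString`).
#' @param window window size (default 10 kb); the sequence must span at
#'   least two windows. Trailing partial windows are dropped.
#' @return a list: `windows` (`GRanges`) and `identity` (symmetric matrix).
#' @export
identityHeatmap <- function(seq, window = 10000L) {
  s <- if (is.character(seq)) seq else as.character(seq)
  if (length(s) != 1L) stop("identityHeatmap expects a single sequence")
  n <- nchar(s)
  nw <- n %/% window
  if (nw < 2L) stop("sequence must span at least 2 windows")
  starts <- (seq_len(nw) - 1L) * window + 1L
  chunks <- substring(s, starts, starts + window - 1L)
  m <- matrix(100, nw, nw)
  for (i in seq_len(nw - 1L)) {
    a <- Biostrings::DNAString(chunks[i])
    for (j in (i + 1L):nw) {
      idF <- {
        aln <- Biostrings::pairwiseAlignment(a, Biostrings::DNAString(chunks[j]),
                                             type = "global")
        100 * Biostrings::nmatch(aln) / max(Biostrings::nchar(aln), 1L)
      }
      idR <- {
        aln <- Biostrings::pairwiseAlignment(
          a, Biostrings::reverseComplement(Biostrings::DNAString(chunks[j])),
          type = "global")
        100 * Biostrings::nmatch(aln) / max(Biostrings::nchar(aln), 1L)
      }
      m[i, j] <- m[j, i] <- max(idF, idR)
    }
  }
  wins <- GenomicRanges::GRanges("seq", IRanges::IRanges(starts,
                                                         starts + window - 1L))
  list(windows = wins, identity = m)
}

#' Detect segmental duplications by seeded self-comparison
#'
#' Exact 15-mer seed matches (satellite-saturated seeds skipped via an
#' occurrence cap) are chained by diagonal into candidate pairs, aligned, and
#' filtered by the four classic criteria: aligned length >= `minLen`,
#' identity > `minIdentity`, gapped fraction of the alignment <= `maxGapped`
#' and satellite-annotated fraction <= `maxSat`.
#'
#' @param genome sequences.
#' @param satAnnotation optional satellite `GRanges` used for the satellite
#'   fraction filter.
#' @param minLen minimum aligned length (default 1 kb).
#' @param minIdentity identity floor as a fraction (default 0.90, exclusive).
#' @param maxGapped maximum gapped fraction (default 0.50).
#' @param maxSat maximum satellite fraction (default 0.70).
#' @param seedK seed k-mer size (default 15).
#' @param maxOcc seed occurrence cap (default 10).
#' @param chainGap maximum seed gap along a diagonal (default 2 kb).
#' @param minSeeds minimum seeds per chain (default 10).
#' @param maxAlign segment cap for the identity alignment (default 20 kb;
#'   longer candidates are scored on their first `maxAlign` bp).
#' @return data.frame of SD pairs: `chromA`, `startA`, `endA`, `chromB`,
#'   `startB`, `endB` (1-based closed), `strand`, `length`, `identity`,
#'   `gappedFrac`, `satFrac`.
#' @export
detectSDs <- function(genome, satAnnotation = NULL, minLen = 1000L,
                      minIdentity = 0.90, maxGapped = 0.50, maxSat = 0.70,
                      seedK = 15L, maxOcc = 10L, chainGap = 2000L,
                      minSeeds = 10L, maxAlign = 20000L) {
  seqs <- .asCharSeqs(genome)
  seeds <- cpp_seed_pairs(seqs, as.integer(seedK), as.integer(maxOcc))
  if (!nrow(seeds)) return(.emptySdFrame())
  seeds$chrom1 <- names(seqs)[seeds$seq1 + 1L]
  seeds$chrom2 <- names(seqs)[seeds$seq2 + 1L]
  ## drop near-diagonal self matches
  self <- seeds$chrom1 == seeds$chrom2 &
    abs(seeds$pos1 - seeds$pos2) < minLen
  seeds <- seeds[!self, , drop = FALSE]
  if (!nrow(seeds)) return(.emptySdFrame())
  diag <- ifelse(seeds$same_strand, seeds$pos2 - seeds$pos1,
                 seeds$pos1 + seeds$pos2)
  grp <- paste(seeds$chrom1, seeds$chrom2, seeds$same_strand, diag)
  out <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < minSeeds) next
    o <- idx[order(seeds$pos1[idx])]
    cl <- cumsum(c(TRUE, diff(seeds$pos1[o]) > chainGap))
    for (ci in unique(cl)) {
      m <- o[cl == ci]
      if (length(m) < minSeeds) next
      a1 <- min(seeds$pos1[m]) + 1L; a2 <- max(seeds$pos1[m]) + seedK
      b1 <- min(seeds$pos2[m]) + 1L; b2 <- max(seeds$pos2[m]) + seedK
      if (a2 - a1 + 1L < minLen) next
      out[[length(out) + 1L]] <- data.frame(
        chromA = seeds$chrom1[m[1L]], startA = a1, endA = a2,
        chromB = seeds$chrom2[m[1L]], startB = b1, endB = b2,
        strand = if (seeds$same_strand[m[1L]]) "+" else "-")
    }
  }
  if (!length(out)) return(.emptySdFrame())
  cand <- do.call(rbind, out)
  ## merge chains on adjacent diagonals that describe the same pair
  grA <- GenomicRanges::GRanges(cand$chromA, IRanges::IRanges(cand$startA, cand$endA))
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(cand))) {
      if (i == j || !keep[j]) next
      sameA <- cand$chromA[i] == cand$chromA[j] &&
        min(cand$endA[i], cand$endA[j]) - max(cand$startA[i], cand$startA[j]) >
          0.5 * (cand$endA[j] - cand$startA[j])
      sameB <- cand$chromB[i] == cand$chromB[j] &&
        min(cand$endB[i], cand$endB[j]) - max(cand$startB[i], cand$startB[j]) >
          0.5 * (cand$endB[j] - cand$startB[j])
      if (sameA && sameB &&
          (cand$endA[i] - cand$startA[i]) >= (cand$endA[j] - cand$startA[j]))
        keep[j] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  res <- list()
  for (i in seq_len(nrow(cand))) {
    lenA <- cand$endA[i] - cand$startA[i] + 1L
    take <- min(lenA, maxAlign)
    sa <- substr(seqs[[cand$chromA[i]]], cand$startA[i],
                 cand$startA[i] + take - 1L)
    sb <- substr(seqs[[cand$chromB[i]]], cand$startB[i],
                 cand$startB[i] + min(cand$endB[i] - cand$startB[i] + 1L,
                                      maxAlign) - 1L)
    if (cand$strand[i] == "-") sb <- .revcomp(sb)
    aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(sa),
                                         Biostrings::DNAString(sb),
                                         type = "global")
    cols <- Biostrings::nchar(aln)
    ident <- Biostrings::nmatch(aln) / cols
    gapped <- 1 - (Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)) / cols
    satFrac <- 0
    if (!is.null(satAnnotation) && length(satAnnotation)) {
      pair <- GenomicRanges::GRanges(
        c(cand$chromA[i], cand$chromB[i]),
        IRanges::IRanges(c(cand$startA[i], cand$startB[i]),
                         c(cand$endA[i], cand$endB[i])))
      covBp <- sum(IRanges::width(GenomicRanges::intersect(
        GenomicRanges::reduce(pair),
        GenomicRanges::reduce(GenomicRanges::granges(satAnnotation)),
        ignore.strand = TRUE)))
      satFrac <- covBp / sum(IRanges::width(pair))
    }
    if (lenA >= minLen && ident > minIdentity && gapped <= maxGapped &&
        satFrac <= maxSat) {
      res[[length(res) + 1L]] <- cbind(cand[i, , drop = FALSE],
        data.frame(length = lenA, identity = 100 * ident,
                   gappedFrac = gapped, satFrac = satFrac))
    }
  }
  if (!length(res)) return(.emptySdFrame())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

.emptySdFrame <- function() {
  data.frame(chromA = character(0), startA = integer(0), endA = integer(0),
             chromB = character(0), startB = integer(0), endB = integer(0),
             strand = character(0), length = integer(0), identity = numeric(0),
             gappedFrac = numeric(0), satFrac = numeric(0))
}
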