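## Gap-read classification, rare-k-mer-scored overlap graphs and gap filling.

#' Anchor read set around an assembly gap
#'
#' Three read kinds, mirroring the gap-filling triage of ultralong reads:
#' kind-1 reads are precisely anchored to a flank and reach the gap boundary
#' (identity >= 0.95, flank-side coverage >= 0.90, read QV >= 20); kind-2
#' reads align only roughly to the gap neighborhood; kind-3 reads have no
#' alignment anywhere and may originate from the gap interior.
#'
#' @slot kind1 data.frame: `read`, `side` (left/right), `strand`, `boundary`
#'   (0-based position of the gap boundary on the plus-oriented read),
#'   `identity`, `coverage`, `qv`.
#' @slot kind2,kind3 character vectors of read names.
#' @export
setClass("AnchorReadSet",
  representation(kind1 = "data.frame", kind2 = "character", kind3 = "character"),
  validity = function(object) {
    k1 <- unique(object@kind1$read)
    if (length(intersect(k1, object@kind2)) ||
        length(intersect(k1, object@kind3)) ||
        length(intersect(object@kind2, object@kind3)))
      return("read kinds must be disjoint")
    TRUE
  })

setMethod("show", "AnchorReadSet", function(object) {
  cat("AnchorReadSet:", nrow(object@kind1), "kind-1 anchors (",
      sum(object@kind1$side == "left"), "left /",
      sum(object@kind1$side == "right"), "right ),",
      length(object@kind2), "kind-2,", length(object@kind3), "kind-3 reads\n")
})

#' Overlap graph over gap-filling reads
#'
#' Directed suffix-prefix overlaps between oriented reads (`read:+` /
#' `read:-` nodes). Every edge is supported by at least one rare k-mer inside
#' the overlap, guarding against false overlaps between repeat copies.
#'
#' @slot edges data.frame: `from`, `to`, `overlap` (bp), `identity`,
#'   `rare` (rare k-mers inside the overlap), `cut` (0-based position on the
#'   oriented target read where novel sequence begins).
#' @slot reads read names present in the graph.
#' @slot minOverlap minimum overlap applied.
#' @export
setClass("OverlapGraph",
  representation(edges = "data.frame", reads = "character",
                 minOverlap = "integer"))

setMethod("show", "OverlapGraph", function(object) {
  cat("OverlapGraph:", length(object@reads), "reads,",
      nrow(object@edges), "rare-k-mer-supported overlap edges (min overlap",
      object@minOverlap, "bp)\n")
})

#' Locate N-gaps in an assembly
#'
#' @param assembly `DNAStringSet`/character sequences.
#' @return `GRanges` of maximal N-runs with an `id` column.
#' @export
findGaps <- function(assembly) {
  seqs <- .asCharSeqs(assembly)
  res <- list()
  for (chr in names(seqs)) {
    m <- gregexpr("N+", seqs[[chr]])[[1L]]
    if (m[1L] == -1L) next
    res[[chr]] <- data.frame(chrom = chr, start = as.integer(m),
                             width = attr(m, "match.length"))
  }
  if (!length(res))
    return(GenomicRanges::GRanges())
  df <- do.call(rbind, res)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, width = df$width))
  gr$id <- sprintf("gap%d", seq_along(gr))
  gr
}

.readQvProxy <- function(identity) pmin(60, -10 * log10(pmax(1 - identity, 1e-6)))

#' Classify reads around a gap into anchor kinds
#'
#' @param paf PAF data.frame of reads aligned to the gapped assembly.
#' @param gap one-row `GRanges` (from [findGaps()]) or list/data.frame with
#'   `chrom`, `start`, `end` (1-based closed, as GRanges).
#' @param allReads character vector of all read names (needed to identify
#'   kind-3 reads without any alignment); `NULL` skips kind-3.
#' @param minIdentity,minCov,minQv kind-1 thresholds (0.95 / 0.90 / 20).
#' @param readQv optional named per-read QV (e.g. mean FASTQ base quality);
#'   when absent an identity-derived proxy is used.
#' @param neighborhood bp around the gap within which rough (kind-2)
#'   alignments are collected.
#' @param boundaryTol how close (bp) a kind-1 alignment must come to the gap
#'   boundary.
#' @return an [AnchorReadSet-class].
#' @export
classifyGapReads <- function(paf, gap, allReads = NULL,
                             minIdentity = 0.95, minCov = 0.90, minQv = 20,
                             readQv = NULL, neighborhood = 50000L,
                             boundaryTol = 100L) {
  if (methods::is(gap, "GRanges")) {
    gchrom <- as.character(GenomeInfoDb::seqnames(gap))[1L]
    gstart <- GenomicRanges::start(gap)[1L]; gend <- GenomicRanges::end(gap)[1L]
  } else {
    gchrom <- gap$chrom; gstart <- gap$start; gend <- gap$end
  }
  if (!any(paf$tname == gchrom))
    stop("gap chromosome '", gchrom, "' not found among alignment targets")
  near <- paf[paf$tname == gchrom &
              paf$tend >= gstart - neighborhood &
              paf$tstart <= gend + neighborhood, , drop = FALSE]
  ident <- pafIdentity(near)
  qv <- if (!is.null(readQv)) unname(readQv[near$qname]) else .readQvProxy(ident)

  k1 <- list()
  for (i in seq_len(nrow(near))) {
    a <- near[i, ]
    side <- NULL
    ## left anchor: alignment reaches the gap start from the left
    if (abs(a$tend - (gstart - 1L)) <= boundaryTol && a$tstart < gstart - 1L)
      side <- "left"
    ## right anchor: alignment starts at the gap end
    if (abs(a$tstart - gend) <= boundaryTol && a$tend > gend) {
      side <- c(side, "right")
    }
    if (is.null(side)) next
    for (s in side) {
      ## flank-side portion of the read (from read start/end to the boundary)
      flankSide <- if ((s == "left") == (a$strand == "+")) a$qend else a$qlen - a$qstart
      cov <- (a$qend - a$qstart) / max(flankSide, 1L)
      boundary <- if (s == "left") {
        if (a$strand == "+") a$qend else a$qlen - a$qstart
      } else {
        if (a$strand == "+") a$qstart else a$qlen - a$qend
      }
      k1[[length(k1) + 1L]] <- data.frame(
        read = a$qname, side = s, strand = a$strand, boundary = boundary,
        identity = ident[i], coverage = cov, qv = qv[i])
    }
  }
  k1 <- if (length(k1)) do.call(rbind, k1) else
    data.frame(read = character(0), side = character(0), strand = character(0),
               boundary = integer(0), identity = numeric(0),
               coverage = numeric(0), qv = numeric(0))
  k1 <- k1[k1$identity >= minIdentity & k1$coverage >= minCov & k1$qv >= minQv,
           , drop = FALSE]
  rownames(k1) <- NULL
  kind2 <- setdiff(unique(near$qname), unique(k1$read))
  kind3 <- if (is.null(allReads)) character(0) else
    setdiff(allReads, unique(paf$qname))
  methods::new("AnchorReadSet", kind1 = k1, kind2 = kind2, kind3 = kind3)
}

.flipNode <- function(node) {
  read <- sub(":[+-]$", "", node)
  ori <- sub("^.*:", "", node)
  paste0(read, ":", ifelse(ori == "+", "-", "+"))
}

.orientedRead <- function(reads, node) {
  read <- sub(":[+-]$", "", node)
  ori <- sub("^.*:", "", node)
  s <- as.character(reads[[read]])
  if (ori == "-") .revcomp(s) else s
}

## Dovetail edges between oriented reads from all-vs-all PAF records.
## `cut` = 0-based position on the oriented target read where sequence not
## already contained in the source read begins.
.dovetailEdges <- function(paf, tol = 100L) {
  out <- list()
  for (i in seq_len(nrow(paf))) {
    a <- paf[i, ]
    qleft <- a$qstart; qright <- a$qlen - a$qend
    if (a$strand == "+") {
      tori <- "+"; tleft <- a$tstart; tright <- a$tlen - a$tend
    } else {
      tori <- "-"; tleft <- a$tlen - a$tend; tright <- a$tstart
    }
    qn <- paste0(a$qname, ":+"); tn <- paste0(a$tname, ":", tori)
    ident <- a$nmatch / max(a$alen, 1L)
    add <- function(from, to, cut) {
      out[[length(out) + 1L]] <<- data.frame(
        from = from, to = to, overlap = a$alen, identity = ident, cut = cut)
    }
    if (qright <= tol && tleft <= tol) {           # q suffix -> t prefix
      add(qn, tn, (a$tlen - tright) + qright)
      add(.flipNode(tn), .flipNode(qn), (a$qlen - qleft) + tleft)
    }
    if (tright <= tol && qleft <= tol) {           # t suffix -> q prefix
      add(tn, qn, a$qend + tright)
      add(.flipNode(qn), .flipNode(tn), (a$tlen - tleft) + qleft)
    }
  }
  if (!length(out))
    return(data.frame(from = character(0), to = character(0),
                      overlap = integer(0), identity = numeric(0),
                      cut = integer(0)))
  do.call(rbind, out)
}

#' Build a rare-k-mer-guarded overlap graph
#'
#' Suffix-prefix (dovetail) overlaps are derived from all-vs-all read
#' alignments; each retained edge must contain at least `minRare` rare
#' k-mers, so that overlaps consisting solely of high-frequency satellite
#' k-mers are rejected.
#'
#' @param reads named `DNAStringSet` of reads.
#' @param overlaps all-vs-all PAF data.frame (e.g. from [minimap2Ava()]).
#' @param rareSet character vector of rare k-mers (see [rareKmers()];
#'   conventionally k = 23 from short-read tables).
#' @param k k-mer size of `rareSet`.
#' @param minOverlap minimum overlap length (bp).
#' @param minRare minimum rare k-mers inside the overlap (default 1).
#' @param tol dovetail hang tolerance (bp).
#' @return an [OverlapGraph-class].
#' @export
buildOverlapGraph <- function(reads, overlaps, rareSet, k = 23L,
                              minOverlap = 2000L, minRare = 1L, tol = 100L) {
  edges <- .dovetailEdges(overlaps, tol = tol)
  edges <- edges[edges$overlap >= minOverlap & edges$from != edges$to,
                 , drop = FALSE]
  edges <- edges[sub(":[+-]$", "", edges$from) != sub(":[+-]$", "", edges$to),
                 , drop = FALSE]
  if (nrow(edges)) {
    ## rare k-mers inside the overlap, taken from the oriented target prefix
    ovlSeq <- character(nrow(edges))
    for (i in seq_len(nrow(edges))) {
      s <- .orientedRead(reads, edges$to[i])
      ovlSeq[i] <- substr(s, 1L, max(edges$cut[i], k))
    }
    hits <- cpp_kmer_hits(ovlSeq, as.integer(k), rareSet)
    edges$rare <- hits[, 2L]
    edges <- edges[edges$rare >= minRare, , drop = FALSE]
    edges <- edges[!duplicated(edges[, c("from", "to")]), , drop = FALSE]
  } else edges$rare <- integer(0)
  rownames(edges) <- NULL
  methods::new("OverlapGraph", edges = edges,
               reads = unique(sub(":[+-]$", "", c(edges$from, edges$to))),
               minOverlap = as.integer(minOverlap))
}

#' Fill a gap from an anchor set and overlap graph
#'
#' A single kind-1 read anchored on both sides short-circuits the search
#' (patch = its substring between the flank hits). Otherwise left-to-right
#' paths through the overlap graph are enumerated (exhaustively up to
#' `maxSteps` expansions, then greedily) and the path with the longest
#' accumulated rare-k-mer support is stitched into the patch; ties break on
#' higher mean identity, then lexicographic node names, for determinism.
#'
#' @param anchors an [AnchorReadSet-class] for this gap.
#' @param graph an [OverlapGraph-class].
#' @param reads named `DNAStringSet` of read sequences.
#' @param assembly optional gapped assembly (`DNAStringSet`); when supplied
#'   together with `gap`, the patch is spliced over the N-run.
#' @param gap the gap `GRanges` row (required with `assembly`).
#' @param maxSteps search budget (default 10000 expansions).
#' @param middleReads reads allowed in path interiors; defaults to the
#'   gap-associated reads (kind-1 anchors and unplaced kind-3 reads), which
#'   keeps the search from drifting into well-anchored flank reads.
#' @return a list: `filled` (logical), `patch` (character or NA), `path`
#'   (oriented node names), `rareScore`, and `assembly` (patched, when input
#'   assembly given). Flanks outside the N-run are never modified.
#' @export
fillGap <- function(anchors, graph, reads, assembly = NULL, gap = NULL,
                    maxSteps = 10000L,
                    middleReads = c(unique(anchors@kind1$read),
                                    anchors@kind3)) {
  k1 <- anchors@kind1
  left <- k1[k1$side == "left", , drop = FALSE]
  right <- k1[k1$side == "right", , drop = FALSE]
  result <- list(filled = FALSE, patch = NA_character_, path = character(0),
                 rareScore = NA_real_)

  ## spanning read short-circuit
  span <- intersect(left$read, right$read)
  if (length(span)) {
    span <- sort(span)[1L]
    l <- left[left$read == span, ][1L, ]
    r <- right[right$read == span, ][1L, ]
    ori <- .orientedRead(reads, paste0(span, ":", l$strand))
    patch <- substr(ori, l$boundary + 1L, r$boundary)
    result <- list(filled = TRUE, patch = patch,
                   path = paste0(span, ":", l$strand), rareScore = Inf)
  } else if (nrow(left) && nrow(right) && nrow(graph@edges)) {
    leftNodes <- paste0(left$read, ":", left$strand)
    rightNodes <- paste0(right$read, ":", right$strand)
    edges <- graph@edges
    edges <- edges[order(-edges$rare, -edges$identity, edges$to), , drop = FALSE]
    adj <- split(seq_len(nrow(edges)), edges$from)
    best <- NULL
    steps <- 0L
    dfs <- function(node, visited, path, score, idsum) {
      if (steps >= maxSteps) return(invisible())
      steps <<- steps + 1L
      if (node %in% rightNodes) {
        cand <- list(path = path, score = score,
                     meanId = idsum / max(length(path) - 1L, 1L))
        if (is.null(best) || cand$score > best$score ||
            (cand$score == best$score && cand$meanId > best$meanId))
          best <<- cand
        return(invisible())
      }
      for (ei in adj[[node]]) {
        nxt <- edges$to[ei]
        nxtBase <- sub(":[+-]$", "", nxt)
        if (nxtBase %in% visited) next
        if (!(nxtBase %in% middleReads) && !(nxt %in% rightNodes)) next
        dfs(nxt, c(visited, nxtBase), c(path, nxt),
            score + edges$rare[ei], idsum + edges$identity[ei])
      }
      invisible()
    }
    for (ln in sort(unique(leftNodes)))
      dfs(ln, sub(":[+-]$", "", ln), ln, 0, 0)
    if (!is.null(best)) {
      path <- best$path
      l <- left[paste0(left$read, ":", left$strand) == path[1L], ][1L, ]
      r <- right[paste0(right$read, ":", right$strand) ==
                   path[length(path)], ][1L, ]
      patch <- substr(.orientedRead(reads, path[1L]), l$boundary + 1L,
                      nchar(as.character(reads[[l$read]])))
      if (length(path) > 1L) {
        for (j in 2:length(path)) {
          key <- which(edges$from == path[j - 1L] & edges$to == path[j])[1L]
          cut <- edges$cut[key]
          s <- .orientedRead(reads, path[j])
          if (j < length(path)) {
            patch <- paste0(patch, substr(s, cut + 1L, nchar(s)))
          } else {
            if (r$boundary > cut) {
              patch <- paste0(patch, substr(s, cut + 1L, r$boundary))
            } else {
              patch <- substr(patch, 1L, nchar(patch) - (cut - r$boundary))
            }
          }
        }
      }
      result <- list(filled = TRUE, patch = patch, path = path,
                     rareScore = best$score)
    }
  }

  if (!is.null(assembly) && result$filled) {
    seqs <- .asCharSeqs(assembly)
    gchrom <- as.character(GenomeInfoDb::seqnames(gap))[1L]
    gstart <- GenomicRanges::start(gap)[1L]; gend <- GenomicRanges::end(gap)[1L]
    seqs[[gchrom]] <- paste0(substr(seqs[[gchrom]], 1L, gstart - 1L),
                             result$patch,
                             substr(seqs[[gchrom]], gend + 1L,
                                    nchar(seqs[[gchrom]])))
    result$assembly <- Biostrings::DNAStringSet(seqs)
  }
  result
}

#' Verify a junction by spanning read support
#'
#' A junction passes when strictly more than `minReads` uniquely aligned,
#' essentially unclipped reads span `position +/- flank` at mapping quality
#' `>= minMapq` (common long-read aligners cap MAPQ at 60, so the classic
#' "MAPQ > 60" support rule is applied as >= 60).
#'
#' @param paf PAF data.frame of reads vs the assembly.
#' @param chrom,position junction location (1-based).
#' @param minReads support threshold (strictly-more-than; default 5).
#' @param minMapq minimum mapping quality (default 60).
#' @param flank bp on each side that a spanning read must cover.
#' @param clipTol maximum unaligned bases tolerated at either read end.
#' @return a list: `pass`, `support`.
#' @export
verifyJunction <- function(paf, chrom, position, minReads = 5L, minMapq = 60L,
                           flank = 1000L, clipTol = 100L) {
  hits <- paf$tname == chrom
  if (!any(hits)) stop("chromosome not found in alignments")
  tl <- paf$tlen[which(hits)[1L]]
  if (position < 1L || position > tl) stop("position out of range")
  a <- paf[hits, , drop = FALSE]
  spans <- a$tstart + 1L <= position - flank & a$tend >= position + flank
  unclipped <- a$qstart <= clipTol & (a$qlen - a$qend) <= clipTol
  support <- sum(spans & unclipped & a$mapq >= minMapq)
  list(pass = support > minReads, support = support)
}
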