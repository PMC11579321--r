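## Canonical k-mer counting and k-mer-derived assembly statistics.

.asCharSeqs <- function(seqs) {
  if (methods::is(seqs, "SyntheticGenome")) seqs <- chromSeqs(seqs)
  if (methods::is(seqs, "XStringSet")) {
    out <- as.character(seqs)
    if (is.null(names(out))) names(out) <- sprintf("seq%d", seq_along(out))
    return(out)
  }
  if (is.character(seqs)) {
    if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
    return(seqs)
  }
  stop("seqs must be a DNAStringSet, SyntheticGenome or character vector")
}

#' Count canonical k-mers
#'
#' Counts every k-mer of the input sequences in canonical form (the
#' lexicographic minimum of the k-mer and its reverse complement). Windows
#' containing non-ACGT characters (e.g. gap Ns) are skipped. Even k is
#' rejected because reverse-complement palindromes make canonicalization
#' ambiguous.
#'
#' @param seqs a `DNAStringSet`, [SyntheticGenome-class] or character vector.
#' @param k odd k-mer size. The conventional choices in this toolkit are
#'   k = 21 (hapmers, QV), k = 23 (gap-filling rare k-mers) and k = 31/151
#'   (trio polish / satellite discovery).
#' @return a [KmerTable-class].
#' @examples
#' countKmers("ACGT", k = 3)  # CGT canonicalizes to ACG
#' @export
countKmers <- function(seqs, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 3L) stop("k must be an integer >= 3")
  if (k %% 2L == 0L) stop("k must be odd (even k is palindrome-ambiguous)")
  seqs <- .asCharSeqs(seqs)
  res <- cpp_count_kmers(seqs, k)
  methods::new("KmerTable", k = k, kmer = as.character(res$kmer),
               count = as.integer(res$count))
}

#' Look up counts of specific k-mers
#'
#' @param table a [KmerTable-class].
#' @param kmers character vector of k-mers (any orientation).
#' @return integer counts; 0 for absent k-mers.
#' @export
kmerCount <- function(table, kmers) {
  stopifnot(methods::is(table, "KmerTable"))
  rc <- .revcomp(kmers)
  canon <- ifelse(kmers <= rc, kmers, rc)
  i <- match(canon, table@kmer)
  out <- table@count[i]
  out[is.na(out)] <- 0L
  stats::setNames(out, kmers)
}

#' Write / read a k-mer table as sorted TSV
#'
#' Plain-text serialization: a `#k=<k>` header line followed by
#' tab-separated `kmer<TAB>count` rows sorted by k-mer.
#' @param table a [KmerTable-class].
#' @param path file path.
#' @return `readKmerTable()` returns a [KmerTable-class].
#' @export
writeKmerTable <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#k=%d", table@k), con)
  writeLines(paste(table@kmer, table@count, sep = "\t"), con)
  invisible(path)
}

#' @rdname writeKmerTable
#' @export
readKmerTable <- function(path) {
  header <- readLines(path, n = 1L)
  k <- as.integer(sub("^#k=", "", header))
  df <- utils::read.table(path, sep = "\t", skip = 1L,
                          col.names = c("kmer", "count"),
                          colClasses = c("character", "integer"))
  methods::new("KmerTable", k = k, kmer = df$kmer, count = df$count)
}

#' Extract parent-specific hapmers
#'
#' Paternal hapmers are k-mers present in the father's table, absent from the
#' mother's, whose depth in the child lies strictly between `dmin` and `dmax`
#' (and symmetrically for maternal hapmers). The depth window discards
#' sequencing-error k-mers (low depth) and collapsed repeats (high depth),
#' following the classic trio-binning rule of depth > 3 and < the child's
#' genome-wide average.
#'
#' @param child,father,mother [KmerTable-class] objects sharing the same k.
#' @param dmin lower child-depth bound (exclusive), default 3.
#' @param dmax upper child-depth bound (exclusive); defaults to the child's
#'   mean k-mer depth.
#' @return a list with elements `paternal` and `maternal`
#'   ([HapmerSet-class] objects; always disjoint).
#' @export
extractHapmers <- function(child, father, mother, dmin = 3,
                           dmax = meanDepth(child)) {
  if (length(unique(c(child@k, father@k, mother@k))) != 1L)
    stop("child, father and mother tables must share the same k")
  .oneSide <- function(inTab, outTab, label) {
    cand <- setdiff(inTab@kmer, outTab@kmer)
    depth <- child@count[match(cand, child@kmer)]
    depth[is.na(depth)] <- 0L
    keep <- depth > dmin & depth < dmax
    methods::new("HapmerSet", parent = label, k = child@k,
                 kmer = cand[keep], dmin = as.numeric(dmin),
                 dmax = as.numeric(dmax))
  }
  list(paternal = .oneSide(father, mother, "paternal"),
       maternal = .oneSide(mother, father, "maternal"))
}

#' Assign reads a parental origin by hapmer counting
#'
#' Each read is assigned to the side with strictly more hapmer hits;
#' ties (including zero hits on both sides) are ambiguous.
#'
#' @param reads `DNAStringSet` or character vector of read sequences.
#' @param paternal,maternal [HapmerSet-class] objects from the same k.
#' @return a data.frame with `read`, `paternalHits`, `maternalHits` and
#'   `origin` (`"paternal"`, `"maternal"` or `"ambiguous"`).
#' @export
binReads <- function(reads, paternal, maternal) {
  if (paternal@k != maternal@k)
    stop("hapmer sets must come from the same k")
  reads <- .asCharSeqs(reads)
  hp <- cpp_kmer_hits(reads, paternal@k, paternal@kmer)[, 2L]
  hm <- cpp_kmer_hits(reads, maternal@k, maternal@kmer)[, 2L]
  origin <- ifelse(hp > hm, "paternal", ifelse(hm > hp, "maternal", "ambiguous"))
  data.frame(read = names(reads), paternalHits = hp, maternalHits = hm,
             origin = origin, row.names = NULL)
}

#' Estimate consensus quality (QV) from k-mers
#'
#' Merqury-style estimator: with `absent` of the assembly's `total` k-mers
#' missing from the read k-mer table, the per-base survival probability is
#' `P = (1 - absent/total)^(1/k)`, the per-base error `E = 1 - P`, and
#' `QV = -10 log10(E)`. Sequences with no absent k-mers are reported at the
#' cap.
#'
#' @param assembly `DNAStringSet`/character assembly sequences.
#' @param readTable [KmerTable-class] built from sequencing reads. A warning
#'   is emitted when its mean depth is below 10, where absent k-mers start to
#'   reflect read dropout rather than assembly error.
#' @param k k-mer size; must match `readTable`.
#' @param cap QV value reported when no absent k-mers are found (default 99).
#' @return a [QVReport-class].
#' @export
estimateQV <- function(assembly, readTable, k = kmerK(readTable), cap = 99) {
  k <- as.integer(k)
  if (k != readTable@k) stop("k does not match the read table")
  assembly <- .asCharSeqs(assembly)
  if (any(nchar(assembly) < k)) stop("assembly sequence shorter than k")
  if (!is.na(meanDepth(readTable)) && meanDepth(readTable) < 10)
    warning("read table mean depth < 10x; QV estimates will be deflated")
  hits <- cpp_kmer_hits(assembly, k, readTable@kmer)
  total <- hits[, 1L]
  absent <- total - hits[, 2L]
  .qv <- function(absent, total) {
    p <- (1 - absent / total)^(1 / k)
    e <- 1 - p
    qv <- ifelse(absent == 0L, cap, -10 * log10(e))
    list(e = e, qv = pmin(qv, cap))
  }
  per <- .qv(absent, total)
  tot <- .qv(sum(absent), sum(total))
  methods::new("QVReport",
               perSeq = data.frame(name = names(assembly), total = total,
                                   absent = absent, error = per$e,
                                   qv = per$qv, row.names = NULL),
               total = sum(total), absent = sum(absent),
               errorRate = tot$e, qv = tot$qv, cap = cap)
}

#' Convert a QV to percent base accuracy
#'
#' @param qv consensus quality value.
#' @return accuracy in percent, `100 * (1 - 10^(-qv/10))`.
#' @examples
#' qvToAccuracy(54.18)  # > 99.999
#' @export
qvToAccuracy <- function(qv) 100 * (1 - 10^(-qv / 10))

#' Rare k-mers of a table
#'
#' k-mers with count strictly below the table's mean depth; used to score
#' read overlaps during gap filling, where high-frequency (satellite) k-mers
#' cause false-positive overlaps.
#'
#' @param table a non-empty [KmerTable-class].
#' @return character vector of canonical rare k-mers.
#' @export
rareKmers <- function(table) {
  stopifnot(methods::is(table, "KmerTable"))
  if (!length(table@kmer)) stop("empty k-mer table")
  table@kmer[table@count < meanDepth(table)]
}

#' Minimum unique k-mer (MUK) track
#'
#' For each tiling window, the smallest substring length `L` in
#' `[kMin, cap]` such that some length-`L` substring *starting inside* the
#' window occurs exactly once genome-wide (counting both strands); `cap` when
#' no such substring exists. Long MUK values flag repetitive regions such as
#' centromeric satellite arrays. Evaluated by a per-window binary search over
#' `L` using canonical 64-bit substring hashing.
#'
#' @param genome `DNAStringSet`/[SyntheticGenome-class]/character sequences.
#' @param window window size in bp (default 100 kb).
#' @param kMin smallest length considered (default 21).
#' @param cap largest length considered and the value reported for windows
#'   with no unique substring (default 100 kb).
#' @return a `GRanges` of windows with a `muk` metadata column.
#' @export
mukTrack <- function(genome, window = 100000L, kMin = 21L, cap = 100000L) {
  seqs <- .asCharSeqs(genome)
  res <- cpp_muk_track(seqs, as.integer(window), as.integer(kMin),
                       as.integer(cap))
  seqlens <- stats::setNames(nchar(seqs), names(seqs))
  gr <- .tileWindows(seqlens, as.integer(window))
  gr$muk <- unlist(res, use.names = FALSE)
  gr
}
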