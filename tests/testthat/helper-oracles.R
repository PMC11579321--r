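## Independent brute-force oracles and small shared fixtures.

revcompChar <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTacgtN", "TGCAtgcaN", s)
    intToUtf8(rev(utf8ToInt(comp)))
  }, character(1L), USE.NAMES = FALSE)
}

randomSeq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## all length-L windows of s in canonical form (NA where the window holds a
## non-ACGT base); reverse complements are read off the reversed-complemented
## sequence at the mirrored position
canonicalWindows <- function(s, L) {
  n <- nchar(s)
  if (n < L) return(character(0))
  fwd <- substring(s, 1:(n - L + 1L), L:n)
  rcs <- revcompChar(s)
  rc <- substring(rcs, (n - L + 1L):1L, n:L)
  canon <- pmin(fwd, rc)
  canon[grepl("[^ACGT]", fwd)] <- NA_character_
  canon
}

## sliding-window canonical k-mer counter, written independently of the
## package's C++ path
bruteCountKmers <- function(seqs, k) {
  all <- unlist(lapply(seqs, canonicalWindows, L = k), use.names = FALSE)
  tab <- table(all[!is.na(all)])
  stats::setNames(as.integer(tab), names(tab))
}

## linear-scan MUK oracle: for each window, the smallest L in [kmin, cap]
## such that some length-L substring starting in the window occurs exactly
## once genome-wide on both strands
bruteMuk <- function(seqs, window, kmin, cap) {
  cap <- as.integer(cap); kmin <- as.integer(kmin)
  lens <- nchar(seqs)
  wins <- list()
  for (chr in names(seqs)) {
    nw <- ceiling(lens[[chr]] / window)
    for (w in seq_len(nw))
      wins[[length(wins) + 1L]] <- list(chr = chr, w = w, muk = NA_integer_)
  }
  for (L in kmin:cap) {
    unresolved <- which(vapply(wins, function(x) is.na(x$muk), logical(1L)))
    if (!length(unresolved)) break
    perSeq <- lapply(seqs, canonicalWindows, L = L)
    tab <- table(unlist(perSeq, use.names = FALSE))
    for (i in unresolved) {
      canon <- perSeq[[wins[[i]]$chr]]
      lo <- (wins[[i]]$w - 1L) * window + 1L
      hi <- min(wins[[i]]$w * window, length(canon))
      if (lo > length(canon) || hi < lo) next
      cc <- canon[lo:hi]
      cc <- cc[!is.na(cc)]
      if (length(cc) && any(tab[cc] == 1L)) wins[[i]]$muk <- L
    }
  }
  vapply(wins, function(x) if (is.na(x$muk)) cap else x$muk, integer(1L))
}

haveMinimap2 <- function() nzchar(Sys.which("minimap2"))

grJaccard <- function(a, b) {
  a <- GenomicRanges::reduce(GenomicRanges::granges(a))
  b <- GenomicRanges::reduce(GenomicRanges::granges(b))
  inter <- sum(IRanges::width(suppressWarnings(
    GenomicRanges::intersect(a, b, ignore.strand = TRUE))))
  uni <- sum(IRanges::width(suppressWarnings(
    GenomicRanges::union(a, b, ignore.strand = TRUE))))
  if (uni == 0) 0 else inter / uni
}

## construct a PAF data.frame row by row (0-based half-open coordinates)
pafRow <- function(qname, qlen, qstart, qend, strand, tname, tlen, tstart,
                   tend, nmatch = NULL, alen = NULL, mapq = 60L) {
  if (is.null(alen)) alen <- qend - qstart
  if (is.null(nmatch)) nmatch <- alen
  data.frame(qname = qname, qlen = qlen, qstart = qstart, qend = qend,
             strand = strand, tname = tname, tlen = tlen, tstart = tstart,
             tend = tend, nmatch = nmatch, alen = alen, mapq = mapq,
             tags = "")
}
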