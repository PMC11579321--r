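## Internal helpers shared across modules.

#' Run code with a temporarily seeded RNG
#'
#' Seeds R's RNG, evaluates `code`, and restores the caller's RNG state so
#' that generator calls are deterministic without perturbing the session.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
.withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Random DNA string
#' @param n length in bp.
#' @return a single character string of A/C/G/T.
#' @keywords internal
#' @noRd
.randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse complement of plain character strings
#' @keywords internal
#' @noRd
.revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTacgtN", "TGCAtgcaN", s)
    intToUtf8(rev(utf8ToInt(comp)))
  }, character(1L), USE.NAMES = FALSE)
}

#' Apply i.i.d. substitutions to a DNA string
#'
#' Each position mutates independently with probability `rate` to one of the
#' three alternative bases. Returns the mutated string.
#' @keywords internal
#' @noRd
.mutate <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  nmut <- stats::rbinom(1L, n, rate)
  if (nmut == 0L) return(seq)
  pos <- sample.int(n, nmut)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    alt <- setdiff(bases, ch[p])
    ch[p] <- alt[sample.int(3L, 1L)]
  }
  paste(ch, collapse = "")
}

#' Tile a set of chromosome lengths into windows
#'
#' 0-based half-open window arithmetic internally; returned as GRanges
#' (1-based closed, the Bioconductor convention).
#' @keywords internal
#' @noRd
.tileWindows <- function(seqlens, window, step = window) {
  grl <- lapply(names(seqlens), function(chr) {
    len <- seqlens[[chr]]
    starts <- seq(0L, max(0L, len - 1L), by = step)
    starts <- starts[starts < len]
    ends <- pmin(starts + window, len)
    GenomicRanges::GRanges(chr, IRanges::IRanges(starts + 1L, ends))
  })
  gr <- suppressWarnings(do.call(c, grl))
  GenomeInfoDb::seqlengths(gr) <- seqlens[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Jaccard index of two interval sets
#' @keywords internal
#' @noRd
.jaccard <- function(a, b) {
  a <- GenomicRanges::reduce(a)
  b <- GenomicRanges::reduce(b)
  inter <- sum(IRanges::width(GenomicRanges::intersect(a, b, ignore.strand = TRUE)))
  uni <- sum(IRanges::width(GenomicRanges::union(a, b, ignore.strand = TRUE)))
  if (uni == 0) return(0)
  inter / uni
}

#' Percent identity between two sequences via global-local alignment
#' @keywords internal
#' @noRd
.alnIdentity <- function(a, b, type = "global") {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = type)
  cols <- Biostrings::nchar(aln)
  100 * Biostrings::nmatch(aln) / cols
}

.checkChrom <- function(x, chroms, what = "chromosome") {
  miss <- setdiff(x, chroms)
  if (length(miss))
    stop("unknown ", what, ": ", paste(miss, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
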