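## Variant filtering, multi-caller SV merging and windowed population scans.

#' Apply GATK-style hard site filters
#'
#' A site FAILs when any of the classic conditions holds:
#' `QD < 2`, `QUAL < 30`, `SOR > 3`, `FS > 60`, `MQ < 40`,
#' `MQRankSum < -12.5`, `ReadPosRankSum < -8`. Absent (NA) metrics never
#' trigger a condition.
#'
#' @param records data.frame with any subset of the metric columns.
#' @return `records` with added `filter` (`PASS` or semicolon-joined reasons).
#' @export
applySiteFilters <- function(records) {
  rules <- list(
    QD = function(x) x < 2.0, QUAL = function(x) x < 30.0,
    SOR = function(x) x > 3.0, FS = function(x) x > 60.0,
    MQ = function(x) x < 40.0, MQRankSum = function(x) x < -12.5,
    ReadPosRankSum = function(x) x < -8.0)
  n <- nrow(records)
  reasons <- vector("list", n)
  for (metric in names(rules)) {
    if (!metric %in% names(records)) next
    v <- records[[metric]]
    if (!is.numeric(v)) stop("malformed record: ", metric, " is not numeric")
    bad <- !is.na(v) & rules[[metric]](v)
    for (i in which(bad)) reasons[[i]] <- c(reasons[[i]], metric)
  }
  records$filter <- vapply(reasons, function(r)
    if (is.null(r)) "PASS" else paste(r, collapse = ";"), character(1L))
  records
}

#' Filter a genotype matrix on missingness, MAF and biallelic state
#'
#' Retains sites with missingness <= `maxMissing`, minor allele frequency
#' >= `minMaf`, and (optionally) exactly two alleles.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param maxMissing maximum site missingness (default 0.10).
#' @param minMaf minimum minor allele frequency (default 0.05).
#' @param biallelicOnly drop sites whose `alt` holds multiple alleles.
#' @return the filtered [GenotypeMatrix-class].
#' @export
filterMatrix <- function(gm, maxMissing = 0.10, minMaf = 0.05,
                         biallelicOnly = TRUE) {
  if (!nrow(gm)) stop("empty genotype matrix")
  keep <- siteMissingness(gm) <= maxMissing & siteMAF(gm) >= minMaf
  keep[is.na(keep)] <- FALSE
  if (biallelicOnly) {
    rd <- SummarizedExperiment::rowData(gm)
    if ("alt" %in% names(rd))
      keep <- keep & !grepl(",", rd$alt, fixed = TRUE) & nzchar(rd$alt)
  }
  gm[keep, ]
}

#' Merge multi-caller SV call sets
#'
#' Calls of identical type on the same chromosome whose positions differ by
#' at most `bin` bp and whose lengths overlap reciprocally by at least
#' `reciprocal` collapse to one record carrying per-caller support. Calls
#' shorter than `minLen` are dropped (translocations exempt). The input is
#' canonically sorted first, so the merge is idempotent and invariant to
#' caller input order.
#'
#' @param callsets list of data.frames with `chrom`, `pos`, `type`, `length`
#'   and `caller` columns (see [simulateSvCallsets()]).
#' @param bin merging bin in bp (default 1000).
#' @param minLen minimum retained SV length (default 50; >= 50 bp retained).
#' @param reciprocal reciprocal length-overlap requirement (default 0.5).
#' @return data.frame of merged calls: `chrom`, `pos` (median), `type`,
#'   `length` (median), `support` (distinct callers), `callers`.
#' @export
mergeSvCallsets <- function(callsets, bin = 1000L, minLen = 50L,
                            reciprocal = 0.5) {
  if (!length(callsets)) stop("at least one callset required")
  if (is.data.frame(callsets)) callsets <- list(callsets)
  all <- do.call(rbind, callsets)
  all <- all[all$type == "TRA" | all$length >= minLen, , drop = FALSE]
  if (!nrow(all))
    return(data.frame(chrom = character(0), pos = integer(0),
                      type = character(0), length = numeric(0),
                      support = integer(0), callers = character(0)))
  all <- all[order(all$type, all$chrom, all$pos, all$length, all$caller),
             , drop = FALSE]
  cluster <- integer(nrow(all))
  cid <- 0L
  anchorPos <- anchorLen <- NA_real_
  for (i in seq_len(nrow(all))) {
    newClust <- i == 1L ||
      all$type[i] != all$type[i - 1L] || all$chrom[i] != all$chrom[i - 1L] ||
      abs(all$pos[i] - anchorPos) > bin ||
      (all$type[i] != "TRA" &&
         min(all$length[i], anchorLen) / max(all$length[i], anchorLen) <
           reciprocal)
    if (newClust) {
      cid <- cid + 1L
      anchorPos <- all$pos[i]; anchorLen <- all$length[i]
    }
    cluster[i] <- cid
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(all)), cluster), function(idx) {
    data.frame(chrom = all$chrom[idx[1L]],
               pos = stats::median(all$pos[idx]),
               type = all$type[idx[1L]],
               length = stats::median(all$length[idx]),
               support = length(unique(all$caller[idx])),
               callers = paste(sort(unique(all$caller[idx])), collapse = ","))
  }))
  out <- out[order(out$chrom, out$pos, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Per-site Weir & Cockerham (1984) variance components for two populations.
## Returns a data.frame with a, b, c components (NA where a population has
## fewer than two non-missing genotypes).
.wcComponents <- function(gm, popA, popB) {
  g <- genotypes(gm)
  pops <- as.character(populations(gm))
  gA <- g[, pops == popA, drop = FALSE]
  gB <- g[, pops == popB, drop = FALSE]
  n1 <- rowSums(!is.na(gA)); n2 <- rowSums(!is.na(gB))
  p1 <- rowSums(gA, na.rm = TRUE) / (2 * pmax(n1, 1L))
  p2 <- rowSums(gB, na.rm = TRUE) / (2 * pmax(n2, 1L))
  h1 <- rowSums(gA == 1L, na.rm = TRUE) / pmax(n1, 1L)
  h2 <- rowSums(gB == 1L, na.rm = TRUE) / pmax(n2, 1L)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- n1 < 2L | n2 < 2L
  a[bad] <- b[bad] <- cc[bad] <- NA_real_
  data.frame(a = a, b = b, c = cc)
}

#' Per-site Weir-Cockerham FST components
#'
#' @param gm a [GenotypeMatrix-class].
#' @param popA,popB population labels.
#' @return data.frame with per-site `a`, `b`, `c` variance components and
#'   `fst` (`a / (a + b + c)`; NA at degenerate sites).
#' @export
fstSites <- function(gm, popA = "pop1", popB = "pop2") {
  comp <- .wcComponents(gm, popA, popB)
  comp$fst <- with(comp, ifelse(a + b + c == 0, NA_real_, a / (a + b + c)))
  comp
}

.slideWindows <- function(seqlens, window, step) {
  .tileWindows(seqlens, as.integer(window), step = as.integer(step))
}

#' Windowed Weir-Cockerham FST
#'
#' Per-site variance components are accumulated over sliding windows
#' (the classic weighted windowed estimator): window FST = sum(a) /
#' sum(a + b + c). Windows without usable sites are omitted. If either
#' population has fewer than two non-missing genotypes at every site, an
#' error is raised.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param popA,popB population labels.
#' @param window,step window and step in bp (defaults 50 kb / 10 kb).
#' @return `GRanges` windows with `fst` and `nSites` columns.
#' @export
fstWindows <- function(gm, popA = "pop1", popB = "pop2",
                       window = 50000L, step = 10000L) {
  comp <- .wcComponents(gm, popA, popB)
  if (all(is.na(comp$a)))
    stop("a population has < 2 non-missing genotypes at every site")
  seqlens <- GenomeInfoDb::seqlengths(SummarizedExperiment::rowRanges(gm))
  wins <- .slideWindows(seqlens, window, step)
  ov <- GenomicRanges::findOverlaps(wins,
                                    SummarizedExperiment::rowRanges(gm))
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  ok <- !is.na(comp$a[sh])
  qh <- qh[ok]; sh <- sh[ok]
  sumBy <- function(v) {
    out <- rep(NA_real_, length(wins))
    s <- tapply(v[sh], qh, sum)
    out[as.integer(names(s))] <- s
    out
  }
  A <- sumBy(comp$a); D <- sumBy(comp$a + comp$b + comp$c)
  n <- tabulate(qh, nbins = length(wins))
  wins$fst <- A / D
  wins$nSites <- n
  wins[n > 0L]
}

#' Genome-wide Hudson FST
#'
#' Ratio-of-sums Hudson estimator; on Balding-Nichols panels its expectation
#' equals the drift parameter F. Used as the independent cross-check of the
#' Weir-Cockerham windows.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param popA,popB population labels.
#' @return a single FST value.
#' @export
hudsonFst <- function(gm, popA = "pop1", popB = "pop2") {
  g <- genotypes(gm)
  pops <- as.character(populations(gm))
  gA <- g[, pops == popA, drop = FALSE]
  gB <- g[, pops == popB, drop = FALSE]
  n1 <- 2 * rowSums(!is.na(gA)); n2 <- 2 * rowSums(!is.na(gB))
  p1 <- rowSums(gA, na.rm = TRUE) / pmax(n1, 1)
  p2 <- rowSums(gB, na.rm = TRUE) / pmax(n2, 1)
  ok <- n1 >= 2 & n2 >= 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num[ok]) / sum(den[ok])
}

#' Windowed nucleotide diversity (pi)
#'
#' Per site, the unbiased heterozygosity `2 p (1-p) n / (n-1)` (n =
#' non-missing allele count) is summed within windows and divided by the
#' full window length (the convention of the standard windowed
#' implementations, which treat unobserved positions as monomorphic).
#'
#' @param gm a [GenotypeMatrix-class].
#' @param pop population label (`NULL` uses all samples).
#' @param window,step window and step in bp (default 50 kb, non-overlapping).
#' @return `GRanges` windows with `pi` and `nSites` columns.
#' @export
piWindows <- function(gm, pop = NULL, window = 50000L, step = window) {
  g <- genotypes(gm)
  if (!is.null(pop)) g <- g[, as.character(populations(gm)) == pop, drop = FALSE]
  n <- 2 * rowSums(!is.na(g))
  p <- rowSums(g, na.rm = TRUE) / pmax(n, 1)
  het <- ifelse(n >= 2, 2 * p * (1 - p) * n / (n - 1), 0)
  seqlens <- GenomeInfoDb::seqlengths(SummarizedExperiment::rowRanges(gm))
  wins <- .slideWindows(seqlens, window, step)
  ov <- GenomicRanges::findOverlaps(wins, SummarizedExperiment::rowRanges(gm))
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  s <- rep(0, length(wins))
  agg <- tapply(het[sh], qh, sum)
  s[as.integer(names(agg))] <- agg
  wins$pi <- s / IRanges::width(wins)
  wins$nSites <- tabulate(qh, nbins = length(wins))
  wins
}

#' Window-wise pi ratio between two populations
#'
#' @param statsA,statsB `GRanges` from [piWindows()] on identical tilings.
#' @return `GRanges` with `piRatio` (A/B; NA where undefined) and
#'   `undefined` flag (B = 0); undefined windows are excluded from ranking
#'   by [topPercentRegions()] via the NA value.
#' @export
piRatio <- function(statsA, statsB) {
  if (length(statsA) != length(statsB) ||
      any(GenomicRanges::start(statsA) != GenomicRanges::start(statsB)) ||
      any(as.character(GenomeInfoDb::seqnames(statsA)) !=
          as.character(GenomeInfoDb::seqnames(statsB))))
    stop("mismatched window tilings")
  out <- GenomicRanges::granges(statsA)
  undef <- statsB$pi == 0
  out$piRatio <- ifelse(undef, NA_real_, statsA$pi / statsB$pi)
  out$undefined <- undef
  out
}

#' Select top-percentile windows and merge them into sweep regions
#'
#' Windows at or above the `(100 - pct)` percentile (cut at the
#' ceiling(n * pct / 100)-th largest value; ties included, with a warning
#' when every window ties) are merged when overlapping or adjacent, and
#' intersected with a gene annotation when given.
#'
#' @param stats `GRanges` with the statistic in `column`.
#' @param pct top percentage (default 1). At least `100 / pct` windows are
#'   required.
#' @param column metadata column to rank (default: first numeric column).
#' @param genes optional `GRanges` with a `gene` (or `name`) column.
#' @return `GRanges` of merged sweep regions with `peak`, `nWindows` and
#'   `genes` columns.
#' @export
topPercentRegions <- function(stats, pct = 1, column = NULL, genes = NULL) {
  mc <- S4Vectors::mcols(stats)
  if (is.null(column))
    column <- names(mc)[vapply(mc, is.numeric, logical(1L))][1L]
  v <- mc[[column]]
  use <- !is.na(v)
  stats <- stats[use]; v <- v[use]
  n <- length(v)
  if (n < ceiling(100 / pct)) stop("too few windows for pct = ", pct)
  kTop <- ceiling(n * pct / 100)
  cut <- sort(v, decreasing = TRUE)[kTop]
  sel <- v >= cut
  if (all(sel))
    warning("all windows tie at the top-percentile threshold; ",
            "every window selected")
  chosen <- stats[sel]
  regions <- GenomicRanges::reduce(chosen, min.gapwidth = 1L,
                                   ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(regions, chosen)
  peak <- vapply(split(v[sel][S4Vectors::subjectHits(ov)],
                       S4Vectors::queryHits(ov)), max, numeric(1L))
  regions$peak <- unname(peak)
  regions$nWindows <- as.integer(unname(table(S4Vectors::queryHits(ov))))
  gene <- rep(NA_character_, length(regions))
  if (!is.null(genes) && length(genes)) {
    nm <- if ("gene" %in% names(S4Vectors::mcols(genes))) genes$gene else
      genes$name
    for (i in seq_along(regions)) {
      hit <- IRanges::overlapsAny(genes, regions[i])
      if (any(hit)) gene[i] <- paste(nm[hit], collapse = ",")
    }
  }
  regions$genes <- gene
  regions
}

.pairwiseR2 <- function(g, i, j) {
  suppressWarnings(stats::cor(g[i, ], g[j, ], use = "pairwise.complete.obs"))^2
}

#' Linkage-disequilibrium decay curve
#'
#' Genotype (composite) r-squared for all site pairs within `maxDist`,
#' averaged in distance bins.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param maxDist maximum pair distance in bp (default 300 kb).
#' @param binWidth distance bin width (default 10 kb).
#' @return data.frame: `dist` (bin midpoint), `meanR2`, `nPairs`.
#' @export
ldDecay <- function(gm, maxDist = 300000L, binWidth = 10000L) {
  g <- genotypes(gm)
  rr <- SummarizedExperiment::rowRanges(gm)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  d <- numeric(0); r2 <- numeric(0)
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    idx <- idx[order(pos[idx])]
    for (ii in seq_along(idx)) {
      for (jj in seq_along(idx)) {
        if (jj <= ii) next
        dd <- pos[idx[jj]] - pos[idx[ii]]
        if (dd > maxDist) break
        d <- c(d, dd)
        r2 <- c(r2, .pairwiseR2(g, idx[ii], idx[jj]))
      }
    }
  }
  bin <- floor(d / binWidth)
  agg <- tapply(r2, bin, mean, na.rm = TRUE)
  data.frame(dist = (as.integer(names(agg)) + 0.5) * binWidth,
             meanR2 = as.numeric(agg),
             nPairs = as.integer(table(bin)))
}

#' LD pruning of sites (sliding-window pairwise r-squared)
#'
#' Within each sliding window of `window` sites (advancing by `step`), one
#' member of every pair with r-squared above `r2max` is removed - the member
#' with the lower MAF (ties: the later site) - until no such pair remains;
#' the classic 50/5/0.2 pruning defaults.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param window window size in sites (default 50).
#' @param step step in sites (default 5).
#' @param r2max maximum retained pairwise r-squared (default 0.2).
#' @return integer vector of retained site indices (row indices of `gm`).
#' @export
ldPrune <- function(gm, window = 50L, step = 5L, r2max = 0.2) {
  g <- genotypes(gm)
  rr <- SummarizedExperiment::rowRanges(gm)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  maf <- siteMAF(gm)
  removed <- logical(nrow(g))
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    if (length(idx) < 2L) next
    starts <- seq(1L, max(1L, length(idx) - 1L), by = step)
    for (s in starts) {
      wIdx <- idx[s:min(s + window - 1L, length(idx))]
      wIdx <- wIdx[!removed[wIdx]]
      if (length(wIdx) < 2L) next
      repeat {
        worst <- NULL; worstR2 <- r2max
        for (ii in seq_along(wIdx)) {
          for (jj in seq_along(wIdx)) {
            if (jj <= ii) next
            r2 <- .pairwiseR2(g, wIdx[ii], wIdx[jj])
            if (!is.na(r2) && r2 > worstR2) {
              worstR2 <- r2; worst <- c(wIdx[ii], wIdx[jj])
            }
          }
        }
        if (is.null(worst)) break
        drop <- if (maf[worst[1L]] < maf[worst[2L]]) worst[1L] else worst[2L]
        removed[drop] <- TRUE
        wIdx <- wIdx[wIdx != drop]
        if (length(wIdx) < 2L) break
      }
    }
  }
  which(!removed)
}
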