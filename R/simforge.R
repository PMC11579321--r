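## Synthetic caprine-like genome generator with full ground truth.
##
## The generator emulates the features this toolkit curates on real data:
## acrocentric chromosomes with terminal telomere arrays, near-end satellite
## arrays (816/702/22-bp monomer families), planted segmental duplications,
## N-gaps, a trio with known haplotype origin, long/short reads with tunable
## error, and a two-population drift panel with planted sweeps.
## All plant coordinates are 0-based half-open (BED convention).

#' Build a genome specification
#'
#' @param chromLengths named integer vector of chromosome lengths (bp).
#' @param telomereCopies tandem copies of the telomere motif per end
#'   (0 disables telomere planting).
#' @param telomereMotif motif planted at the 5' end (default `TTAGGG`; the 3'
#'   end receives its reverse complement, `CCCTAA`).
#' @param centromeres data.frame with columns `chrom`, `start` (0-based),
#'   `monomerLength` (e.g. 816, 702 or 22), `copies`, `divergence`
#'   (per-copy substitution rate).
#' @param sds data.frame of duplication plants with columns `srcChrom`,
#'   `srcStart`, `srcEnd`, `tgtChrom`, `tgtStart`, `divergence`.
#' @param gaps data.frame with columns `chrom`, `start`, `end`; consumed by
#'   [plantGaps()].
#' @param rdna optional data.frame with columns `chrom`, `start`,
#'   `unitLength`, `copies`.
#' @param seed integer seed; identical spec + seed gives byte-identical output.
#' @return a [GenomeSpec-class].
#' @export
genomeSpec <- function(chromLengths, telomereCopies = 12L,
                       telomereMotif = "TTAGGG",
                       centromeres = NULL, sds = NULL, gaps = NULL,
                       rdna = NULL, seed = 1L) {
  empty <- function(x, cols) {
    if (is.null(x)) {
      x <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    }
    x
  }
  methods::new("GenomeSpec",
    chromLengths = stats::setNames(as.integer(chromLengths), names(chromLengths)),
    telomereCopies = as.integer(telomereCopies),
    telomereMotif = telomereMotif,
    centromeres = empty(centromeres,
                        c("chrom", "start", "monomerLength", "copies", "divergence")),
    sds = empty(sds, c("srcChrom", "srcStart", "srcEnd", "tgtChrom",
                       "tgtStart", "divergence")),
    gaps = empty(gaps, c("chrom", "start", "end")),
    rdna = empty(rdna, c("chrom", "start", "unitLength", "copies")),
    seed = as.integer(seed))
}

.plantIntervalsOf <- function(spec) {
  ints <- list()
  L <- spec@chromLengths
  tlen <- 6L * spec@telomereCopies
  if (spec@telomereCopies > 0L) {
    for (chr in names(L)) {
      ints[[length(ints) + 1L]] <- data.frame(
        chrom = chr, start = c(0L, L[[chr]] - tlen), end = c(tlen, L[[chr]]),
        id = paste0("telomere_", chr, c("_5p", "_3p")))
    }
  }
  cen <- spec@centromeres
  if (nrow(cen)) {
    ints[[length(ints) + 1L]] <- data.frame(
      chrom = cen$chrom, start = cen$start,
      end = cen$start + cen$monomerLength * cen$copies,
      id = sprintf("centromere_%s_sat%d", cen$chrom, cen$monomerLength))
  }
  sds <- spec@sds
  if (nrow(sds)) {
    ints[[length(ints) + 1L]] <- data.frame(
      chrom = sds$tgtChrom, start = sds$tgtStart,
      end = sds$tgtStart + (sds$srcEnd - sds$srcStart),
      id = sprintf("sd%d_target", seq_len(nrow(sds))))
  }
  if (nrow(spec@rdna)) {
    ints[[length(ints) + 1L]] <- data.frame(
      chrom = spec@rdna$chrom, start = spec@rdna$start,
      end = spec@rdna$start + spec@rdna$unitLength * spec@rdna$copies,
      id = sprintf("rdna_%s", spec@rdna$chrom))
  }
  if (nrow(spec@gaps)) {
    ints[[length(ints) + 1L]] <- data.frame(
      chrom = spec@gaps$chrom, start = spec@gaps$start, end = spec@gaps$end,
      id = sprintf("gap%d", seq_len(nrow(spec@gaps))))
  }
  if (!length(ints)) return(data.frame(chrom = character(0), start = integer(0),
                                       end = integer(0), id = character(0)))
  do.call(rbind, ints)
}

#' Generate a synthetic genome from a specification
#'
#' Chromosome backbones are i.i.d. random DNA; planted features overwrite the
#' backbone exactly where the returned truth annotation says. Plants must lie
#' within chromosome bounds and must not overlap each other; violations are
#' rejected with the offending feature identifiers.
#'
#' @param spec a [GenomeSpec-class].
#' @return a [SyntheticGenome-class]; the truth `GRanges` carries `label`
#'   (`telomere`/`centromere`/`sd`/`rdna`), `id` and (for satellites) `family`
#'   columns, and the satellite family monomer sequences in its metadata.
#' @export
makeGenome <- function(spec) {
  stopifnot(methods::is(spec, "GenomeSpec"))
  L <- spec@chromLengths
  ints <- .plantIntervalsOf(spec)
  if (nrow(ints)) {
    bad <- ints$start < 0L | ints$end > L[ints$chrom] | ints$start >= ints$end
    if (any(bad))
      stop("planted features out of chromosome bounds: ",
           paste(ints$id[bad], collapse = ", "))
    gr <- GenomicRanges::GRanges(ints$chrom,
                                 IRanges::IRanges(ints$start + 1L, ints$end))
    ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
    if (length(ov))
      stop("overlapping planted features: ",
           paste(unique(paste(ints$id[S4Vectors::queryHits(ov)],
                              ints$id[S4Vectors::subjectHits(ov)], sep = "/")),
                 collapse = ", "))
  }
  .withSeed(spec@seed, {
    seqs <- vapply(L, .randomDNA, character(1L))
    truth <- list()
    addTruth <- function(chrom, start0, end0, label, id, family = NA_character_) {
      truth[[length(truth) + 1L]] <<- data.frame(
        chrom = chrom, start = start0, end = end0, label = label, id = id,
        family = family)
    }
    tlen <- 6L * spec@telomereCopies
    if (spec@telomereCopies > 0L) {
      m5 <- strrep(spec@telomereMotif, spec@telomereCopies)
      m3 <- strrep(.revcomp(spec@telomereMotif), spec@telomereCopies)
      for (chr in names(L)) {
        substr(seqs[[chr]], 1L, tlen) <- m5
        substr(seqs[[chr]], L[[chr]] - tlen + 1L, L[[chr]]) <- m3
        addTruth(chr, 0L, tlen, "telomere", paste0("telomere_", chr, "_5p"))
        addTruth(chr, L[[chr]] - tlen, L[[chr]], "telomere",
                 paste0("telomere_", chr, "_3p"))
      }
    }
    ## one monomer sequence per satellite family, shared across chromosomes
    monomers <- character(0)
    cen <- spec@centromeres
    if (nrow(cen)) {
      for (ml in sort(unique(cen$monomerLength)))
        monomers[[paste0("sat", ml)]] <- .randomDNA(ml)
      for (i in seq_len(nrow(cen))) {
        fam <- paste0("sat", cen$monomerLength[i])
        copies <- vapply(seq_len(cen$copies[i]), function(j)
          .mutate(monomers[[fam]], cen$divergence[i]), character(1L))
        arr <- paste(copies, collapse = "")
        s0 <- cen$start[i]
        substr(seqs[[cen$chrom[i]]], s0 + 1L, s0 + nchar(arr)) <- arr
        addTruth(cen$chrom[i], s0, s0 + nchar(arr), "centromere",
                 sprintf("centromere_%s_%s", cen$chrom[i], fam), fam)
      }
    }
    if (nrow(spec@rdna)) {
      for (i in seq_len(nrow(spec@rdna))) {
        unit <- .randomDNA(spec@rdna$unitLength[i])
        arr <- strrep(unit, spec@rdna$copies[i])
        s0 <- spec@rdna$start[i]
        substr(seqs[[spec@rdna$chrom[i]]], s0 + 1L, s0 + nchar(arr)) <- arr
        addTruth(spec@rdna$chrom[i], s0, s0 + nchar(arr), "rdna",
                 sprintf("rdna_%s", spec@rdna$chrom[i]))
      }
    }
    sds <- spec@sds
    if (nrow(sds)) {
      for (i in seq_len(nrow(sds))) {
        src <- substr(seqs[[sds$srcChrom[i]]], sds$srcStart[i] + 1L, sds$srcEnd[i])
        dup <- .mutate(src, sds$divergence[i])
        t0 <- sds$tgtStart[i]
        substr(seqs[[sds$tgtChrom[i]]], t0 + 1L, t0 + nchar(dup)) <- dup
        addTruth(sds$srcChrom[i], sds$srcStart[i], sds$srcEnd[i], "sd",
                 sprintf("sd%d_source", i))
        addTruth(sds$tgtChrom[i], t0, t0 + nchar(dup), "sd",
                 sprintf("sd%d_target", i))
      }
    }
    tdf <- if (length(truth)) do.call(rbind, truth) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 label = character(0), id = character(0), family = character(0))
    gr <- GenomicRanges::GRanges(
      tdf$chrom, IRanges::IRanges(tdf$start + 1L, tdf$end),
      label = tdf$label, id = tdf$id, family = tdf$family)
    GenomeInfoDb::seqlevels(gr) <- names(L)
    GenomeInfoDb::seqlengths(gr) <- unname(L)
    S4Vectors::metadata(gr)$monomers <- monomers
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- names(L)
    methods::new("SyntheticGenome", seqs = dna, truth = gr, seed = spec@seed)
  })
}

#' Simulate a trio of haplotypes from a base genome
#'
#' Each of the four parental haplotypes receives independent SNVs at rate
#' `hetRate` per bp; the child inherits one paternal and one maternal
#' haplotype byte-identically. The default k for downstream hapmer extraction
#' is 21.
#'
#' @param genome a [SyntheticGenome-class] (or `DNAStringSet`).
#' @param hetRate per-bp SNV probability, in `[0, 0.05]`.
#' @param seed integer seed.
#' @return a [TrioHaplotypes-class].
#' @export
makeTrio <- function(genome, hetRate = 1e-3, seed = 1L) {
  if (hetRate < 0 || hetRate > 0.05) stop("hetRate must lie in [0, 0.05]")
  base <- .asCharSeqs(genome)
  .withSeed(seed, {
    bases <- c("A", "C", "G", "T")
    mkHap <- function(parent, hap) {
      vars <- list()
      seqs <- base
      for (chr in names(base)) {
        n <- nchar(base[[chr]])
        nv <- stats::rbinom(1L, n, hetRate)
        if (nv == 0L) next
        pos <- sort(sample.int(n, nv))
        ref <- substring(base[[chr]], pos, pos)
        ok <- ref %in% bases
        pos <- pos[ok]; ref <- ref[ok]
        if (!length(pos)) next
        alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1L))
        s <- seqs[[chr]]
        for (j in seq_along(pos)) substr(s, pos[j], pos[j]) <- alt[j]
        seqs[[chr]] <- s
        vars[[chr]] <- data.frame(parent = parent, hap = hap, chrom = chr,
                                  pos = pos, ref = ref, alt = alt,
                                  row.names = NULL)
      }
      list(seq = Biostrings::DNAStringSet(seqs),
           vars = if (length(vars)) do.call(rbind, vars) else
             data.frame(parent = character(0), hap = integer(0),
                        chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0)))
    }
    f1 <- mkHap("father", 1L); f2 <- mkHap("father", 2L)
    m1 <- mkHap("mother", 1L); m2 <- mkHap("mother", 2L)
    choice <- c(sample.int(2L, 1L), sample.int(2L, 1L))
    fhaps <- list(f1, f2); mhaps <- list(m1, m2)
    vars <- rbind(f1$vars, f2$vars, m1$vars, m2$vars)
    rownames(vars) <- NULL
    methods::new("TrioHaplotypes",
                 father = list(f1$seq, f2$seq), mother = list(m1$seq, m2$seq),
                 childPaternal = fhaps[[choice[1L]]]$seq,
                 childMaternal = mhaps[[choice[2L]]]$seq,
                 variants = vars, hetRate = hetRate, choice = choice)
  })
}

#' Build a read profile
#'
#' @param platform `"long"` (default) or `"short"`.
#' @param meanLength,sdLength read length distribution; long-read defaults
#'   18,950 / 4,000 bp, short-read 150 / 0.
#' @param subRate,insRate,delRate per-base substitution and single-base
#'   indel rates (defaults 0: error-free).
#' @param depth target fold coverage.
#' @return a [ReadProfile-class].
#' @export
readProfile <- function(platform = c("long", "short"),
                        meanLength = NULL, sdLength = NULL,
                        subRate = 0, insRate = 0, delRate = 0, depth = 30) {
  platform <- match.arg(platform)
  if (is.null(meanLength)) meanLength <- if (platform == "long") 18950 else 150
  if (is.null(sdLength)) sdLength <- if (platform == "long") 4000 else 0
  methods::new("ReadProfile", platform = platform, meanLength = meanLength,
               sdLength = sdLength, subRate = subRate, insRate = insRate,
               delRate = delRate, depth = depth)
}

.applyReadErrors <- function(seq, profile) {
  seq <- .mutate(seq, profile@subRate)
  if (profile@insRate <= 0 && profile@delRate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  ndel <- stats::rbinom(1L, n, profile@delRate)
  if (ndel > 0L) ch <- ch[-sample.int(length(ch), ndel)]
  nins <- stats::rbinom(1L, n, profile@insRate)
  if (nins > 0L) {
    at <- sample.int(length(ch) + 1L, nins, replace = TRUE)
    ins <- sample(c("A", "C", "G", "T"), nins, replace = TRUE)
    for (j in order(at, decreasing = TRUE))
      ch <- append(ch, ins[j], after = at[j] - 1L)
  }
  paste(ch, collapse = "")
}

#' Simulate sequencing reads with truth origin
#'
#' Read start positions are uniform, strands random, and total bases
#' approximate `depth` times the genome length. Each read records its true
#' source sequence, interval and strand in `mcols`.
#'
#' @param seqs sequences to sample from (`DNAStringSet`,
#'   [SyntheticGenome-class] or character); names identify the haplotype or
#'   chromosome of origin.
#' @param profile a [ReadProfile-class].
#' @param seed integer seed.
#' @return a `DNAStringSet` of reads with metadata columns `source`, `start`,
#'   `end` (1-based truth interval on the source) and `strand`.
#' @export
simulateReads <- function(seqs, profile = readProfile(), seed = 1L) {
  seqs <- .asCharSeqs(seqs)
  if (!length(seqs)) stop("empty sequence set")
  .withSeed(seed, {
    lens <- nchar(seqs)
    total <- sum(as.numeric(lens))
    nReads <- max(1L, round(profile@depth * total / profile@meanLength))
    src <- sample(names(seqs), nReads, replace = TRUE, prob = lens / total)
    out <- character(nReads)
    meta <- data.frame(source = src, start = integer(nReads),
                       end = integer(nReads), strand = character(nReads))
    for (i in seq_len(nReads)) {
      L <- lens[[src[i]]]
      rl <- if (profile@sdLength > 0)
        round(stats::rnorm(1L, profile@meanLength, profile@sdLength)) else
        round(profile@meanLength)
      rl <- max(50L, min(rl, L))
      if (rl == L) {
        s <- 1L; e <- L
      } else {
        ## fragment starts over an extended range, clipped at the ends, so
        ## chromosome ends receive full coverage
        s0 <- sample.int(L + rl - 1L, 1L) - rl + 1L
        s <- max(1L, s0); e <- min(L, s0 + rl - 1L)
        if (e - s + 1L < 50L) { if (s == 1L) e <- 50L else s <- e - 49L }
      }
      frag <- substr(seqs[[src[i]]], s, e)
      st <- sample(c("+", "-"), 1L)
      if (st == "-") frag <- .revcomp(frag)
      out[i] <- .applyReadErrors(frag, profile)
      meta$start[i] <- s; meta$end[i] <- e; meta$strand[i] <- st
    }
    reads <- Biostrings::DNAStringSet(out)
    names(reads) <- sprintf("read%06d", seq_len(nReads))
    S4Vectors::mcols(reads) <- S4Vectors::DataFrame(meta)
    reads
  })
}

#' Replace intervals with N-gaps, withholding the truth sequence
#'
#' Gap intervals (0-based half-open) are replaced by N-runs of identical
#' length so that assembly length is conserved; the withheld sequences are
#' returned for round-trip evaluation of gap filling.
#'
#' @param genome a [SyntheticGenome-class] or `DNAStringSet`.
#' @param gaps data.frame with `chrom`, `start`, `end`; defaults to the gap
#'   plants recorded in the genome's spec when generated via [genomeSpec()].
#' @return a list: `assembly` (gapped `DNAStringSet`), `withheld` (named
#'   `DNAStringSet` of removed sequence) and `gaps` (`GRanges`).
#' @export
plantGaps <- function(genome, gaps) {
  seqs <- .asCharSeqs(genome)
  stopifnot(all(c("chrom", "start", "end") %in% names(gaps)))
  .checkChrom(gaps$chrom, names(seqs))
  if (any(gaps$start < 0L | gaps$end > nchar(seqs)[gaps$chrom] |
          gaps$start >= gaps$end))
    stop("gap intervals out of bounds")
  gr <- GenomicRanges::GRanges(gaps$chrom,
                               IRanges::IRanges(gaps$start + 1L, gaps$end))
  if (length(GenomicRanges::findOverlaps(gr, drop.self = TRUE)))
    stop("overlapping gaps")
  withheld <- character(nrow(gaps))
  for (i in seq_len(nrow(gaps))) {
    chr <- gaps$chrom[i]
    withheld[i] <- substr(seqs[[chr]], gaps$start[i] + 1L, gaps$end[i])
    substr(seqs[[chr]], gaps$start[i] + 1L, gaps$end[i]) <-
      strrep("N", gaps$end[i] - gaps$start[i])
  }
  wh <- Biostrings::DNAStringSet(withheld)
  names(wh) <- sprintf("gap%d_%s_%d_%d", seq_len(nrow(gaps)), gaps$chrom,
                       gaps$start, gaps$end)
  gr$id <- names(wh)
  list(assembly = Biostrings::DNAStringSet(seqs), withheld = wh, gaps = gr)
}

#' Build a two-population drift model
#'
#' @param sampleSizes diploid samples per population (length 2).
#' @param F Balding-Nichols drift parameter per population (scalar recycled).
#' @param nSites number of biallelic sites.
#' @param sweeps data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `factor` (diversity multiplier in `(0, 1]`) and `pop` (1 or 2).
#' @param missingRate per-genotype missingness.
#' @return a [PopulationModel-class].
#' @export
populationModel <- function(sampleSizes = c(50L, 50L), F = 0.2,
                            nSites = 5000L, sweeps = NULL, missingRate = 0) {
  if (is.null(sweeps))
    sweeps <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), factor = numeric(0), pop = integer(0))
  methods::new("PopulationModel", sampleSizes = as.integer(sampleSizes),
               F = rep_len(F, 2L), nSites = as.integer(nSites),
               sweeps = sweeps, missingRate = missingRate)
}

#' Simulate a two-population genotype panel under drift
#'
#' Per site, an ancestral frequency is drawn once; each population's
#' frequency comes from the Balding-Nichols Beta distribution with drift F,
#' so the expected between-population FST equals F. Genotypes are binomial
#' draws; inside sweep intervals the target population's expected
#' heterozygosity is multiplied by the sweep factor (frequencies are pulled
#' toward the nearest fixation, giving a known truth interval).
#'
#' @param genome coordinate space: a [SyntheticGenome-class], `DNAStringSet`,
#'   or named integer vector of chromosome lengths.
#' @param model a [PopulationModel-class].
#' @param seed integer seed.
#' @return a [GenotypeMatrix-class]; site truth (ancestral and per-population
#'   frequencies, sweep membership) is kept in `rowData`, and the sweep table
#'   in `metadata(x)$sweeps`.
#' @export
simulatePopulation <- function(genome, model, seed = 1L) {
  seqlens <- if (is.numeric(genome)) genome else
    stats::setNames(nchar(.asCharSeqs(genome)), names(.asCharSeqs(genome)))
  stopifnot(methods::is(model, "PopulationModel"))
  .withSeed(seed, {
    nS <- model@nSites
    chrom <- sample(names(seqlens), nS, replace = TRUE,
                    prob = seqlens / sum(seqlens))
    pos <- vapply(chrom, function(chr) sample.int(seqlens[[chr]], 1L), integer(1L))
    o <- order(match(chrom, names(seqlens)), pos)
    chrom <- chrom[o]; pos <- pos[o]
    pAnc <- stats::runif(nS, 0.05, 0.95)
    popFreq <- matrix(0, nS, 2L)
    for (j in 1:2) {
      Fj <- model@F[j]
      popFreq[, j] <- if (Fj == 0) pAnc else
        stats::rbeta(nS, pAnc * (1 - Fj) / Fj, (1 - pAnc) * (1 - Fj) / Fj)
    }
    inSweep <- matrix(FALSE, nS, 2L)
    sw <- model@sweeps
    if (nrow(sw)) {
      for (i in seq_len(nrow(sw))) {
        hit <- chrom == sw$chrom[i] & pos > sw$start[i] & pos <= sw$end[i]
        p <- popFreq[hit, sw$pop[i]]
        h <- sw$factor[i] * 2 * p * (1 - p)
        lo <- (1 - sqrt(pmax(0, 1 - 2 * h))) / 2
        popFreq[hit, sw$pop[i]] <- ifelse(p <= 0.5, lo, 1 - lo)
        inSweep[hit, sw$pop[i]] <- TRUE
      }
    }
    nTot <- sum(model@sampleSizes)
    geno <- matrix(NA_integer_, nS, nTot)
    popLab <- rep(c("pop1", "pop2"), model@sampleSizes)
    colIdx <- split(seq_len(nTot), popLab)
    for (j in 1:2) {
      idx <- colIdx[[paste0("pop", j)]]
      geno[, idx] <- stats::rbinom(nS * length(idx), 2L, rep(popFreq[, j],
                                                             length(idx)))
    }
    if (model@missingRate > 0) {
      mask <- stats::runif(length(geno)) < model@missingRate
      geno[mask] <- NA_integer_
    }
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nS, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1L))
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    GenomeInfoDb::seqlevels(gr) <- names(seqlens)
    GenomeInfoDb::seqlengths(gr) <- unname(seqlens)
    gm <- GenotypeMatrix(geno, gr, popLab,
                         alleles = data.frame(ref = ref, alt = alt))
    SummarizedExperiment::rowData(gm)$pAncestral <- pAnc
    SummarizedExperiment::rowData(gm)$pPop1 <- popFreq[, 1L]
    SummarizedExperiment::rowData(gm)$pPop2 <- popFreq[, 2L]
    SummarizedExperiment::rowData(gm)$inSweep <- inSweep[, 1L] | inSweep[, 2L]
    S4Vectors::metadata(gm)$sweeps <- sw
    gm
  })
}

#' Simulate imperfect multi-caller SV call sets
#'
#' Each simulated caller reports the truth set minus random false negatives,
#' plus random false positives, with breakpoint positions perturbed by up to
#' `jitter` bp; the scaffolding needed to exercise multi-caller merging.
#' Truth SVs must be >= 50 bp (translocations exempt).
#'
#' @param truthSvs data.frame with `chrom`, `pos`, `type`, `length`.
#' @param jitter maximum absolute positional perturbation (bp).
#' @param fnRate,fpRate per-caller false-negative rate and false-positive
#'   fraction (relative to the truth count).
#' @param nCallers number of callers to simulate.
#' @param seqlens named lengths used to place false positives.
#' @param seed integer seed.
#' @return a list of per-caller data.frames with a `caller` column.
#' @export
simulateSvCallsets <- function(truthSvs, jitter = 0, fnRate = 0, fpRate = 0,
                               nCallers = 3L, seqlens = NULL, seed = 1L) {
  if (jitter < 0) stop("jitter must be >= 0")
  bad <- truthSvs$length < 50 & truthSvs$type != "TRA"
  if (any(bad)) stop("truth SVs must be >= 50 bp (except TRA)")
  .withSeed(seed, {
    lapply(seq_len(nCallers), function(ci) {
      keep <- stats::runif(nrow(truthSvs)) >= fnRate
      calls <- truthSvs[keep, , drop = FALSE]
      if (nrow(calls) && jitter > 0)
        calls$pos <- calls$pos +
          sample(seq(-round(jitter), round(jitter)), nrow(calls), replace = TRUE)
      nFP <- round(fpRate * nrow(truthSvs))
      if (nFP > 0) {
        if (is.null(seqlens)) seqlens <- stats::setNames(
          max(truthSvs$pos + truthSvs$length) * 2L, truthSvs$chrom[1L])
        fp <- data.frame(
          chrom = sample(names(seqlens), nFP, replace = TRUE),
          pos = sample.int(min(seqlens), nFP),
          type = sample(c("DEL", "INS", "DUP", "INV"), nFP, replace = TRUE),
          length = sample(50:2000, nFP, replace = TRUE))
        calls <- rbind(calls, fp)
      }
      calls$caller <- sprintf("caller%d", ci)
      rownames(calls) <- NULL
      calls
    })
  })
}

#' Write a genome (FASTA, 60-column wrap) and its truth annotation (BED)
#'
#' @param genome a [SyntheticGenome-class].
#' @param fasta,bed output paths (`NULL` skips the file).
#' @return invisibly, the paths written.
#' @export
writeGenome <- function(genome, fasta = NULL, bed = NULL) {
  if (!is.null(fasta))
    Biostrings::writeXStringSet(chromSeqs(genome), fasta, width = 60L)
  if (!is.null(bed)) {
    tr <- truth(genome)
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(tr)),
                     start = GenomicRanges::start(tr) - 1L,
                     end = GenomicRanges::end(tr),
                     name = paste(tr$label, tr$id, sep = ":"))
    utils::write.table(df, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(c(fasta = fasta, bed = bed))
}

#' Write reads as FASTQ (constant Q30 qualities)
#'
#' @param reads `DNAStringSet` from [simulateReads()].
#' @param path output FASTQ path.
#' @return invisibly, `path`.
#' @export
writeReadsFastq <- function(reads, path) {
  quals <- Biostrings::PhredQuality(
    vapply(Biostrings::width(reads), function(w) strrep("?", w), character(1L)))
  q <- Biostrings::QualityScaledDNAStringSet(reads, quals)
  Biostrings::writeQualityScaledXStringSet(q, path)
  invisible(path)
}
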