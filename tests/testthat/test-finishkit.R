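test_that("gap reads are classified into the three anchor kinds", {
  ## gap on chr1 at [10000, 20000) 0-based -> GRanges 10001..20000
  gap <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 20000))
  paf <- rbind(
    ## kind-1 left anchor: high identity, reaches the gap start
    pafRow("r1", 20000, 0, 12000, "+", "chr1", 50000, 0, 10000,
           nmatch = 11900, alen = 12000),
    ## kind-2: rough alignment near the gap (identity 0.90)
    pafRow("r2", 20000, 0, 10000, "+", "chr1", 50000, 2000, 9500,
           nmatch = 9000, alen = 10000),
    ## unrelated alignment far away
    pafRow("r4", 20000, 0, 20000, "+", "chr1", 50000, 150000, 170000))
  anch <- classifyGapReads(paf, gap, allReads = c("r1", "r2", "r3", "r4"),
                           neighborhood = 50000)
  expect_equal(anch@kind1$read, "r1")
  expect_equal(anch@kind1$side, "left")
  expect_equal(anch@kind1$boundary, 12000)   # + strand left anchor -> qend
  expect_true("r2" %in% anch@kind2)
  expect_equal(anch@kind3, "r3")             # no alignment anywhere
  ## coverage below threshold demotes an anchor to kind-2
  paf3 <- pafRow("r5", 40000, 9000, 12000, "+", "chr1", 50000, 7050, 10000,
                 nmatch = 2990, alen = 3000)
  anch3 <- classifyGapReads(paf3, gap)
  expect_equal(nrow(anch3@kind1), 0)         # coverage 3000/12000 < 0.9
  expect_true("r5" %in% anch3@kind2)
  expect_error(classifyGapReads(paf, list(chrom = "chrX", start = 1,
                                          end = 10)), "not found")
})

test_that("junction verification requires strictly more than minReads spanning", {
  mkSpan <- function(n, mapq = 60L, clipped = FALSE) {
    do.call(rbind, lapply(seq_len(n), function(i)
      pafRow(paste0("s", i), 10000, if (clipped) 2000 else 0,
             if (clipped) 8000 else 10000, "+", "chr1", 100000,
             45000 + i * 10, 55000 + i * 10, mapq = mapq)))
  }
  expect_true(verifyJunction(mkSpan(6), "chr1", 50000)$pass)
  expect_false(verifyJunction(mkSpan(5), "chr1", 50000)$pass)  # boundary
  expect_false(verifyJunction(mkSpan(8, mapq = 30L), "chr1", 50000)$pass)
  ## all reads clipped at the junction -> no support
  expect_false(verifyJunction(mkSpan(8, clipped = TRUE), "chr1", 50000)$pass)
  expect_error(verifyJunction(mkSpan(6), "chr1", 1e9), "out of range")
})

test_that("telomere detection needs > minCopies tandem copies at an end", {
  s12 <- paste0(strrep("CCCTAA", 12), randomSeq(5000, 21))
  calls <- detectTelomeres(c(chr1 = s12))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$end, "5p")
  expect_equal(calls$motif, "CCCTAA")
  expect_equal(calls$length, 72)
  ## exactly 10 copies -> no call (strict >)
  s10 <- paste0(strrep("CCCTAA", 10), randomSeq(5000, 22))
  expect_equal(nrow(detectTelomeres(c(chr1 = s10))), 0)
  ## interior arrays outside endScan are not called
  sMid <- paste0(randomSeq(20000, 23), strrep("TTAGGG", 15),
                 randomSeq(20000, 24))
  expect_equal(nrow(detectTelomeres(c(chr1 = sMid), endScan = 10000)), 0)
  ## an interruption <= 6 bp does not reset the copy count
  sInt <- paste0(strrep("TTAGGG", 6), "ACGT", strrep("TTAGGG", 6),
                 randomSeq(3000, 25))
  ci <- detectTelomeres(c(chr1 = sInt))
  expect_equal(ci$copies, 12)
})

test_that("simulated capped genomes yield exactly two calls per chromosome", {
  g <- makeGenome(genomeSpec(c(chr1 = 40000L, chr2 = 40000L, chr3 = 40000L),
                             telomereCopies = 12L, seed = 31L))
  calls <- detectTelomeres(g)
  expect_equal(nrow(calls), 6)
  expect_equal(as.integer(table(calls$chrom)), rep(2L, 3))
  ## calls match the truth annotation exactly
  tr <- truth(g); tel <- tr[tr$label == "telomere"]
  got <- GenomicRanges::GRanges(calls$chrom,
                                IRanges::IRanges(calls$start, calls$stop))
  expect_equal(grJaccard(got, tel), 1)
})

test_that("telomere-bearing contigs patch truncated ends back to the original", {
  g <- makeGenome(genomeSpec(c(chr1 = 120000L), telomereCopies = 12L,
                             seed = 99L))
  orig <- as.character(chromSeqs(g)[["chr1"]])
  trunc <- substr(orig, 2501, nchar(orig))
  contig <- substr(orig, 1, 25000)
  res <- patchChromosomeEnds(c(chr1 = trunc), c(tig = contig),
                             endWindow = 40000, minOverlap = 10000)
  expect_equal(res$report$action, "patched")
  expect_identical(as.character(res$assembly[["chr1"]]), orig)
  ## reverse-complement contig is also placed
  resrc <- patchChromosomeEnds(c(chr1 = trunc), c(tig = revcompChar(contig)),
                               endWindow = 40000, minOverlap = 10000)
  expect_identical(as.character(resrc$assembly[["chr1"]]), orig)
  ## a contig without telomere is never placed
  mid <- substr(orig, 50000, 80000)
  resm <- patchChromosomeEnds(c(chr1 = orig), c(tig = mid),
                              endWindow = 40000, minOverlap = 10000)
  expect_equal(resm$report$action, "no_telomere")
  ## telomere contig matching only the interior stays unplaced
  telMid <- paste0(strrep("TTAGGG", 15), substr(orig, 50000, 80000))
  resu <- patchChromosomeEnds(c(chr1 = orig), c(tig = telMid),
                              endWindow = 20000, minOverlap = 5000)
  expect_true(resu$report$action %in% c("unplaced", "ambiguous"))
})

test_that("overlap edges require rare k-mer support inside the overlap", {
  ## two reads sharing a unique 5-kb suffix-prefix overlap
  u <- randomSeq(15000, 51)
  readA <- substr(u, 1, 10000)
  readB <- substr(u, 5001, 15000)
  reads <- Biostrings::DNAStringSet(c(A = readA, B = readB))
  paf <- pafRow("A", 10000, 5000, 10000, "+", "B", 10000, 0, 5000)
  rare <- kmers(countKmers(substr(u, 6000, 6100), 23))
  gr <- buildOverlapGraph(reads, paf, rare, k = 23, minOverlap = 2000)
  expect_true(any(gr@edges$from == "A:+" & gr@edges$to == "B:+"))
  expect_equal(gr@edges$overlap[1], 5000)
  ## same topology but rare set disjoint from the overlap -> edge rejected
  rareElse <- kmers(countKmers(randomSeq(200, 77), 23))
  gr2 <- buildOverlapGraph(reads, paf, rareElse, k = 23, minOverlap = 2000)
  expect_equal(nrow(gr2@edges), 0)
})

test_that("a single spanning anchor read short-circuits gap filling", {
  skip_if_not(haveMinimap2(), "minimap2 not on PATH")
  g <- makeGenome(genomeSpec(c(chr1 = 60000L), telomereCopies = 0L, seed = 61L))
  pg <- plantGaps(g, data.frame(chrom = "chr1", start = 25000, end = 33000))
  reads <- simulateReads(g, readProfile(meanLength = 20000, sdLength = 0,
                                        depth = 8), seed = 3L)
  paf <- minimap2Align(reads, pg$assembly, preset = "map-ont")
  anch <- classifyGapReads(paf, pg$gaps[1], allReads = names(reads))
  emptyGraph <- new("OverlapGraph",
                    edges = data.frame(from = character(0), to = character(0),
                                       overlap = integer(0),
                                       identity = numeric(0),
                                       cut = integer(0), rare = integer(0)),
                    reads = character(0), minOverlap = 2000L)
  res <- fillGap(anch, emptyGraph, reads, assembly = pg$assembly,
                 gap = pg$gaps[1])
  expect_true(res$filled)
  expect_identical(res$patch, as.character(pg$withheld[[1]]))
  ## flanks outside the N-run are never modified
  filled <- as.character(res$assembly[["chr1"]])
  orig <- as.character(chromSeqs(g)[["chr1"]])
  expect_identical(substr(filled, 1, 25000), substr(orig, 1, 25000))
  expect_identical(substr(filled, 33001, 60000), substr(orig, 33001, 60000))
})

test_that("path scoring prefers the longest accumulated rare-k-mer support", {
  ## diamond graph: left anchor L, two middle reads M1/M2, right anchor R;
  ## M1 carries much more rare support and must be chosen
  edges <- data.frame(
    from = c("L:+", "L:+", "M1:+", "M2:+"),
    to = c("M1:+", "M2:+", "R:+", "R:+"),
    overlap = 3000L, identity = 1,
    cut = c(3000L, 3000L, 3000L, 3000L),
    rare = c(1000L, 200L, 1000L, 200L))
  graph <- new("OverlapGraph", edges = edges,
               reads = c("L", "M1", "M2", "R"), minOverlap = 2000L)
  seqs <- Biostrings::DNAStringSet(c(
    L = randomSeq(6000, 1), M1 = randomSeq(6000, 2),
    M2 = randomSeq(6000, 3), R = randomSeq(6000, 4)))
  anch <- new("AnchorReadSet",
              kind1 = data.frame(read = c("L", "R"), side = c("left", "right"),
                                 strand = "+", boundary = c(2000L, 4000L),
                                 identity = 1, coverage = 1, qv = 60),
              kind2 = character(0), kind3 = c("M1", "M2"))
  res <- fillGap(anch, graph, seqs)
  expect_true(res$filled)
  expect_equal(res$path, c("L:+", "M1:+", "R:+"))
  expect_equal(res$rareScore, 2000)
  ## patch stitches L after its boundary, M1 and R up to its boundary
  expected <- paste0(substr(as.character(seqs[["L"]]), 2001, 6000),
                     substr(as.character(seqs[["M1"]]), 3001, 6000),
                     substr(as.character(seqs[["R"]]), 3001, 4000))
  expect_identical(res$patch, expected)
})

test_that("polish region classification partitions chromosomes by trigger", {
  ## uniform deep high-MAPQ coverage -> one high-quality segment away from ends
  paf <- do.call(rbind, lapply(0:19, function(i)
    pafRow(paste0("r", i), 5000, 0, 5000, "+", "chr1", 20000,
           i * 1000, i * 1000 + 5000)))
  paf$tend <- pmin(paf$tend, 20000L)
  rc <- classifyPolishRegions(paf, c(chr1 = 20000L), window = 1000,
                              minReads = 3)
  expect_equal(sum(IRanges::width(rc)), 20000)          # partition
  expect_true(all(c("low", "high") %in% rc$label) || all(rc$label == "high"))
  ## a window covered by only 2 reads is low-quality
  paf2 <- paf[1:2, ]
  rc2 <- classifyPolishRegions(paf2, c(chr1 = 20000L), window = 1000)
  expect_true(all(rc2$label[GenomicRanges::start(rc2) > 10000] == "low"))
  ## both-end-clipped pileup flags its window
  pafc <- do.call(rbind, lapply(1:6, function(i)
    pafRow(paste0("c", i), 8000, 2000, 6000, "+", "chr1", 20000,
           9000, 13000)))
  rc3 <- classifyPolishRegions(rbind(paf, pafc), c(chr1 = 20000L),
                               window = 1000)
  flagged <- rc3[grepl("clipped", rc3$reason)]
  expect_true(length(flagged) > 0)
  expect_true(any(GenomicRanges::start(flagged) <= 13000 &
                  GenomicRanges::end(flagged) >= 9000))
})

test_that("pileup polishing corrects planted errors and then stabilises", {
  skip_if_not(haveMinimap2(), "minimap2 not on PATH")
  g <- makeGenome(genomeSpec(c(chr1 = 60000L), telomereCopies = 0L, seed = 13L))
  orig <- as.character(chromSeqs(g)[["chr1"]])
  asm <- orig
  substr(asm, 30000, 30000) <- if (substr(orig, 30000, 30000) == "A") "C" else "A"
  reads <- simulateReads(g, readProfile(meanLength = 10000, sdLength = 0,
                                        depth = 20), seed = 3L)
  tab <- countKmers(reads, 21)
  qvBefore <- suppressWarnings(estimateQV(c(chr1 = asm), tab))@qv
  bam <- mapReadsBam(reads, c(chr1 = asm))
  pp <- pileupPolish(c(chr1 = asm), bam)
  expect_equal(nrow(pp$edits), 1)
  expect_equal(pp$edits$pos, 30000)
  polished <- as.character(pp$assembly[["chr1"]])
  expect_identical(polished, orig)
  qvAfter <- suppressWarnings(estimateQV(c(chr1 = polished), tab))@qv
  expect_gt(qvAfter, qvBefore)
  ## idempotence: a second round against the polished assembly edits nothing
  bam2 <- mapReadsBam(reads, c(chr1 = polished))
  pp2 <- pileupPolish(c(chr1 = polished), bam2)
  expect_equal(nrow(pp2$edits), 0)
  ## region restriction: an edit outside the target regions is not applied
  away <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
  pp3 <- pileupPolish(c(chr1 = asm), bam, regions = away)
  expect_equal(nrow(pp3$edits), 0)
})
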