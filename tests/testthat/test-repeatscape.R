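test_that("monomer discovery recovers unit length from pure and divergent arrays", {
  ## pure 5-mer array: one unit, length 5, a rotation of ACGTT
  arr <- strrep("ACGTT", 2000)
  units <- discoverSatelliteUnits(c(c1 = arr), k = 21, minCount = 20)
  expect_equal(nrow(units), 1)
  expect_equal(units$length, 5L)
  expect_equal(units$monomer, canonicalRotation("ACGTT"))
  ## 816-bp planted monomer at 2% per-copy divergence: exact length recovery,
  ## rotation- and strand-invariant
  g <- makeGenome(genomeSpec(
    c(chr1 = 150000L), telomereCopies = 0L,
    centromeres = data.frame(chrom = "chr1", start = 20000,
                             monomerLength = 816, copies = 120,
                             divergence = 0.02), seed = 5L))
  u816 <- discoverSatelliteUnits(chromSeqs(g), k = 21, minCount = 20)
  expect_true(816L %in% u816$length)
  mono <- S4Vectors::metadata(truth(g))$monomers[["sat816"]]
  rec <- u816$monomer[u816$length == 816L][1]
  expect_equal(rec, canonicalRotation(mono))
  expect_error(discoverSatelliteUnits(
    new("KmerTable", k = 21L, kmer = character(0), count = integer(0))),
    "empty")
})

test_that("three planted families yield units of length 816, 702 and 22", {
  cen <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                    start = c(10000, 130000, 10000),
                    monomerLength = c(816, 22, 702),
                    copies = c(120, 3500, 120),
                    divergence = c(0.01, 0.01, 0.01))
  g <- makeGenome(genomeSpec(c(chr1 = 250000L, chr2 = 120000L),
                             telomereCopies = 0L, centromeres = cen,
                             seed = 21L))
  units <- discoverSatelliteUnits(chromSeqs(g), k = 21, minCount = 20)
  expect_true(all(c(816L, 702L, 22L) %in% units$length))
})

test_that("satellite annotation covers arrays end-to-end and nothing else", {
  mono <- substr(randomSeq(200, 71), 1, 50)
  arr <- strrep(mono, 50)
  flank1 <- randomSeq(20000, 72); flank2 <- randomSeq(20000, 73)
  g <- c(chr1 = paste0(flank1, arr, flank2))
  ann <- annotateSatellites(g, data.frame(family = "u", monomer = mono))
  expect_equal(length(ann), 1)
  expect_equal(GenomicRanges::start(ann), 20001)
  expect_equal(GenomicRanges::end(ann), 20000 + 50 * 50)
  expect_equal(ann$identity, 100)
  expect_gte(ann$copies, 50)
  ## 5% divergent copies still covered end-to-end at minIdentity 0.8
  set.seed(9)
  copies <- vapply(1:50, function(i) T2Tkit:::.mutate(mono, 0.05),
                   character(1))
  g2 <- c(chr1 = paste0(flank1, paste(copies, collapse = ""), flank2))
  ann2 <- annotateSatellites(g2, data.frame(family = "u", monomer = mono),
                             minIdentity = 0.8)
  cov <- sum(IRanges::width(ann2))
  expect_gte(cov, 0.95 * 50 * 50)
  expect_true(all(GenomicRanges::start(ann2) >= 20001 - 50 &
                  GenomicRanges::end(ann2) <= 20000 + 50 * 50 + 50))
})

test_that("complexity is depressed in repeats and high in random sequence", {
  arr <- strrep("ACGGT", 2000)
  g <- c(chr1 = paste0(randomSeq(10000, 81), arr, strrep("A", 10000)))
  cx <- complexityTrack(g, window = 10000)
  v <- cx$complexity
  expect_true(all(v > 0 & v <= 1))
  expect_equal(which.min(v), 3L)          # all-A window is the minimum
  expect_gt(v[1], v[2])                   # random > satellite
})

test_that("window depth tracks average per-base coverage", {
  expect_equal(windowDepthTrack(emptyPaf(), c(chr1 = 20000L),
                                window = 5000)$depth, rep(0, 4))
  ## uniform 10x coverage laid down at a fixed stride
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(seq(1, 99501, by = 50),
                                                width = 500))
  dt <- windowDepthTrack(gr, c(chr1 = 100000L), window = 5000)
  expect_equal(length(dt), 20)
  inner <- dt$depth[2:19]
  expect_true(all(abs(inner - 10) <= 1))
})

test_that("centromere calls integrate evidence with truth-level accuracy", {
  g <- makeGenome(genomeSpec(
    c(chr1 = 1000000L, chr2 = 600000L), telomereCopies = 12L,
    centromeres = data.frame(chrom = "chr1", start = 100000,
                             monomerLength = 816, copies = 500,
                             divergence = 0.02), seed = 55L))
  seqlens <- stats::setNames(Biostrings::width(chromSeqs(g)),
                             names(chromSeqs(g)))
  tr <- truth(g)
  cenTruth <- tr[tr$label == "centromere"]
  set.seed(1)
  mkReads <- function(n, chr, lo, hi)
    GenomicRanges::GRanges(chr, IRanges::IRanges(sample(lo:hi, n, TRUE),
                                                 width = 200))
  bg <- suppressWarnings(c(mkReads(2000, "chr1", 1, 999800),
                           mkReads(1200, "chr2", 1, 599800)))
  enr <- mkReads(6000, "chr1", GenomicRanges::start(cenTruth),
                 GenomicRanges::end(cenTruth) - 200)
  chip <- windowDepthTrack(c(bg, enr), seqlens, window = 5000)
  meth <- windowDepthTrack(c(bg, enr), seqlens, window = 20000)
  mono <- S4Vectors::metadata(tr)$monomers[["sat816"]]
  ann <- annotateSatellites(g, data.frame(family = "sat816", monomer = mono))
  satd <- satelliteDensityTrack(ann, seqlens, window = 10000)
  cx <- complexityTrack(g, window = 10000)
  calls <- callCentromeres(list(chip = chip, methylation = meth,
                                satellite = satd, complexity = cx),
                           satAnnotation = ann)
  ## exactly one call, on the chromosome carrying the planted array
  expect_equal(length(calls), 1)
  expect_equal(as.character(GenomeInfoDb::seqnames(calls)), "chr1")
  expect_gte(calls$nEvidence, 2)
  expect_equal(calls$dominantFamily, "sat816")
  expect_gte(grJaccard(calls, cenTruth), 0.8)
  ## no satellite/ChIP enrichment -> zero calls
  g0 <- makeGenome(genomeSpec(c(chr1 = 400000L), telomereCopies = 0L,
                              seed = 77L))
  sl0 <- c(chr1 = 400000L)
  chip0 <- windowDepthTrack(mkReads(800, "chr1", 1, 399800), sl0,
                            window = 5000)
  cx0 <- complexityTrack(g0, window = 10000)
  calls0 <- callCentromeres(list(chip = chip0, complexity = cx0))
  expect_equal(length(calls0), 0)
})

test_that("identity heatmaps are symmetric with an exact diagonal", {
  set.seed(6)
  base <- randomSeq(2000, 61)
  div <- T2Tkit:::.mutate(base, 0.05)
  s <- paste0(base, div, randomSeq(2000, 62), revcompChar(base))
  ih <- identityHeatmap(s, window = 2000)
  m <- ih$identity
  expect_equal(dim(m), c(4L, 4L))
  expect_equal(diag(m), rep(100, 4))
  expect_true(all(abs(m - t(m)) <= 0.5))
  ## planted 5% divergence -> identity 95 +/- 1
  expect_lt(abs(m[1, 2] - 95), 1)
  ## reverse-complement copy is recognised via the minus strand
  expect_gt(m[1, 4], 99)
  ## unrelated windows sit far below
  expect_lt(m[1, 3], 80)
  expect_error(identityHeatmap(randomSeq(1500, 63), window = 2000),
               "2 windows")
})

test_that("segmental duplication detection applies the four filters", {
  ## planted exact 10-kb duplication -> one pair at identity 100
  g <- makeGenome(genomeSpec(
    c(chr1 = 200000L, chr2 = 120000L), telomereCopies = 0L,
    sds = data.frame(srcChrom = "chr1", srcStart = 50000, srcEnd = 60000,
                     tgtChrom = "chr2", tgtStart = 30000, divergence = 0),
    seed = 33L))
  sd <- detectSDs(g)
  expect_equal(nrow(sd), 1)
  expect_equal(sd$chromA, "chr1"); expect_equal(sd$chromB, "chr2")
  expect_gte(sd$identity, 99.9)
  expect_gte(sd$length, 9900)
  tr <- truth(g)
  src <- tr[tr$id == "sd1_source"]; tgt <- tr[tr$id == "sd1_target"]
  expect_gte(grJaccard(GenomicRanges::GRanges(sd$chromA,
                                              IRanges::IRanges(sd$startA,
                                                               sd$endA)),
                       src), 0.95)
  expect_gte(grJaccard(GenomicRanges::GRanges(sd$chromB,
                                              IRanges::IRanges(sd$startB,
                                                               sd$endB)),
                       tgt), 0.95)
  ## 12% divergent copy fails the >90% identity filter
  g2 <- makeGenome(genomeSpec(
    c(chr1 = 200000L, chr2 = 120000L), telomereCopies = 0L,
    sds = data.frame(srcChrom = "chr1", srcStart = 50000, srcEnd = 60000,
                     tgtChrom = "chr2", tgtStart = 30000, divergence = 0.12),
    seed = 33L))
  expect_equal(nrow(detectSDs(g2)), 0)
  ## duplication that is mostly satellite fails the satellite filter
  mono <- substr(randomSeq(100, 91), 1, 40)
  block <- paste0(strrep(mono, 45), randomSeq(400, 92))   # ~82% satellite
  g3 <- c(chr1 = paste0(randomSeq(30000, 93), block, randomSeq(30000, 94),
                        block, randomSeq(30000, 95)))
  ann3 <- annotateSatellites(g3, data.frame(family = "m", monomer = mono))
  sat3 <- detectSDs(g3, satAnnotation = ann3, maxOcc = 200)
  expect_equal(nrow(sat3), 0)
  ## without the annotation the tandem pairs are reported
  nosat3 <- detectSDs(g3, maxOcc = 200)
  expect_gte(nrow(nosat3), 1)
})

test_that("SD detection is precise on random sequence", {
  g <- c(chr1 = randomSeq(600000, 101), chr2 = randomSeq(400000, 102))
  expect_equal(nrow(detectSDs(g)), 0)
})
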