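mkGm <- function(geno, pops, pos = NULL, chrom = "chr1", seqlen = 1000000L,
                 alleles = NULL) {
  if (is.null(pos)) pos <- seq_len(nrow(geno)) * 100L
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(seqlen, chrom)
  GenotypeMatrix(geno, gr, pops, alleles = alleles)
}

test_that("hard site filters trigger on each metric and ignore NAs", {
  rec <- data.frame(QD = c(10, 1.5, NA), QUAL = c(100, 100, 100),
                    SOR = c(1, 1, 1), FS = c(10, 10, 10),
                    MQ = c(60, 60, 60), MQRankSum = c(0, 0, -13),
                    ReadPosRankSum = c(0, 0, 0))
  out <- applySiteFilters(rec)
  expect_equal(out$filter, c("PASS", "QD", "MQRankSum"))
  multi <- applySiteFilters(data.frame(QD = 1, QUAL = 10))
  expect_equal(multi$filter, "QD;QUAL")
  expect_error(applySiteFilters(data.frame(QD = "oops")), "malformed")
})

test_that("matrix filtering applies the missingness/MAF/biallelic rules", {
  n <- 100L
  g <- matrix(0L, nrow = 5, ncol = n)
  g[1, 1:11] <- NA_integer_    # 11% missing -> removed
  g[2, 1:10] <- NA_integer_; g[2, 11:40] <- 1L   # 10% missing, MAF .17 -> kept
  g[3, 1:8] <- 1L              # MAF 0.04 -> removed
  g[4, 1:10] <- 1L             # MAF 0.05 -> retained (boundary)
  g[5, 1:30] <- 1L             # triallelic -> removed
  alle <- data.frame(ref = rep("A", 5), alt = c("T", "T", "T", "T", "T,G"))
  gm <- mkGm(g, rep(c("pop1", "pop2"), each = n / 2), alleles = alle)
  kept <- filterMatrix(gm)
  expect_equal(nrow(kept), 2L)
  expect_equal(GenomicRanges::start(SummarizedExperiment::rowRanges(kept)),
               c(200L, 400L))
  ## self-consistency: the output satisfies its own thresholds
  expect_true(all(siteMissingness(kept) <= 0.10))
  expect_true(all(siteMAF(kept) >= 0.05))
  expect_error(filterMatrix(gm[0, ]), "empty")
})

test_that("SV merging collapses within-bin same-type calls and drops short SVs", {
  a <- data.frame(chrom = "chr1", pos = c(1000, 30000, 60000),
                  type = "DEL", length = c(300, 300, 45), caller = "A")
  b <- data.frame(chrom = "chr1", pos = c(1500, 31500), type = "DEL",
                  length = c(300, 300), caller = "B")
  m <- mergeSvCallsets(list(a, b), bin = 1000)
  ## pos 1000/1500 merge (500 <= bin); 30000/31500 stay apart; 45-bp dropped
  expect_equal(nrow(m), 3)
  expect_equal(m$support, c(2L, 1L, 1L))
  ## different types never merge
  c1 <- data.frame(chrom = "chr1", pos = 1000, type = "INS", length = 300,
                   caller = "C")
  m2 <- mergeSvCallsets(list(a[1, ], c1), bin = 1000)
  expect_equal(nrow(m2), 2)
  ## idempotent and order-invariant
  mFlip <- mergeSvCallsets(list(b, a), bin = 1000)
  expect_equal(m[, c("chrom", "pos", "type", "support")],
               mFlip[, c("chrom", "pos", "type", "support")])
  m3 <- mergeSvCallsets(list(transform(m, caller = callers)), bin = 1000)
  expect_equal(nrow(m3), nrow(m))
  expect_lte(nrow(m), nrow(a) + nrow(b))
})

test_that("per-site Weir-Cockerham components match the hand-computed toy", {
  ## nA = nB = 10 diploids, pA = 0.9 (8 hom-alt + 2 het), pB = 0.1
  ## (8 hom-ref + 2 het); independently transcribed 1984 algebra gives
  ## a = 0.31556, b = -0.00556, c = 0.1 -> FST = 0.7696477
  gA <- c(rep(2L, 8), rep(1L, 2))
  gB <- c(rep(0L, 8), rep(1L, 2))
  gm <- mkGm(matrix(c(gA, gB), nrow = 1), rep(c("pop1", "pop2"), each = 10))
  s <- fstSites(gm)
  expect_equal(s$a, 0.31555556, tolerance = 1e-6)
  expect_equal(s$b, -0.00555556, tolerance = 1e-4)
  expect_equal(s$c, 0.1, tolerance = 1e-8)
  expect_equal(s$fst, 0.7696477, tolerance = 1e-6)
})

test_that("windowed FST behaves at the differentiation extremes", {
  set.seed(5)
  nS <- 400L
  ## identical allele frequencies, large n -> FST ~ 0
  p <- runif(nS, 0.2, 0.8)
  g <- matrix(rbinom(nS * 100, 2, rep(p, 100)), nrow = nS)
  gm <- mkGm(g, rep(c("pop1", "pop2"), each = 50),
             pos = sort(sample.int(900000, nS)))
  fw <- fstWindows(gm)
  expect_lt(abs(weighted.mean(fw$fst, fw$nSites)), 0.02)
  ## fixed difference at every site -> FST -> 1
  gfix <- cbind(matrix(0L, nS, 50), matrix(2L, nS, 50))
  gmf <- mkGm(gfix, rep(c("pop1", "pop2"), each = 50),
              pos = sort(sample.int(900000, nS)))
  ff <- fstWindows(gmf)
  expect_true(all(ff$fst > 0.99))
  ## windows without sites are omitted
  expect_true(all(ff$nSites > 0))
  gmDegenerate <- mkGm(matrix(c(NA_integer_, NA, 0L, 0L), nrow = 1),
                       c("pop1", "pop1", "pop2", "pop2"))
  expect_error(fstWindows(gmDegenerate), "non-missing")
})

test_that("pi equals the all-pairs haplotype difference oracle exactly", {
  set.seed(7)
  nHap <- 10L; nS <- 30L
  hap <- matrix(rbinom(nS * nHap, 1, 0.4), nrow = nS)
  geno <- hap[, seq(1, nHap, 2)] + hap[, seq(2, nHap, 2)]
  pos <- sort(sample.int(49000, nS))
  gm <- mkGm(geno, rep("pop1", nHap / 2), pos = pos, seqlen = 50000L)
  pw <- piWindows(gm, window = 50000L)
  ## brute force: mean pairwise difference per site, summed over sites
  tot <- 0
  for (s in seq_len(nS)) {
    d <- 0; np <- 0
    for (i in seq_len(nHap - 1)) for (j in (i + 1):nHap) {
      d <- d + as.integer(hap[s, i] != hap[s, j]); np <- np + 1
    }
    tot <- tot + d / np
  }
  expect_equal(pw$pi[1], tot / 50000, tolerance = 1e-12)
  ## monomorphic window -> 0
  gm0 <- mkGm(matrix(0L, 5, 10), rep("pop1", 10), seqlen = 50000L)
  expect_equal(piWindows(gm0, window = 50000L)$pi[1], 0)
  ## two haplotypes differing at one site -> 1 / window
  gm1 <- mkGm(matrix(1L, 1, 1), "pop1", pos = 10L, seqlen = 50000L)
  expect_equal(piWindows(gm1, window = 50000L)$pi[1], 1 / 50000)
})

test_that("pi ratio flags undefined windows and preserves the tiling", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 50001),
                                                        c(50000, 100000)))
  a <- gr; a$pi <- c(0.002, 0.001)
  b <- gr; b$pi <- c(0.001, 0)
  pr <- piRatio(a, b)
  expect_equal(pr$piRatio[1], 2)
  expect_true(is.na(pr$piRatio[2]) && pr$undefined[2])
  expect_error(piRatio(a, b[1]), "mismatched")
})

test_that("top-percent selection keeps ties and merges adjacent windows", {
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges((0:199) * 10000 + 1,
                                                (0:199) * 10000 + 50000))
  v <- seq_len(200) / 200
  gr$fst <- v
  top <- topPercentRegions(gr, pct = 1, column = "fst")
  expect_equal(sum(top$nWindows), 2L)   # ceiling(200 * 0.01) = 2, no ties
  expect_equal(top$peak, 1)
  ## all-equal values: every window ties at the cut, with a warning
  gr$fst <- rep(0.5, 200)
  expect_warning(all <- topPercentRegions(gr, pct = 1, column = "fst"),
                 "tie")
  expect_equal(sum(all$nWindows), 200L)
  expect_error(topPercentRegions(gr[1:50], pct = 1, column = "fst"),
               "too few")
  ## gene intersection
  gr$fst <- v
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1995000, 1999000),
                                  gene = "GENE1")
  topg <- topPercentRegions(gr, pct = 1, column = "fst", genes = genes)
  expect_equal(topg$genes, "GENE1")
})

test_that("LD decay uses only pairs within range and detects duplication", {
  set.seed(9)
  g <- matrix(rbinom(20 * 100, 2, 0.5), nrow = 20)
  g[2, ] <- g[1, ]                      # duplicated column at distance 5 kb
  pos <- c(1000, 6000, seq(20000, 300000, length.out = 18))
  gm <- mkGm(g, rep("pop1", 100), pos = as.integer(pos))
  ld <- ldDecay(gm, maxDist = 300000, binWidth = 10000)
  expect_equal(ld$meanR2[ld$dist == 5000], 1)
  ## independent sites at n = 100 -> near-null background
  far <- ld$meanR2[ld$dist > 20000]
  expect_lt(mean(far), 0.05)
  ## pairs beyond maxDist excluded entirely
  gm2 <- mkGm(g[1:2, ], rep("pop1", 100), pos = c(1000L, 400000L))
  expect_equal(nrow(ldDecay(gm2, maxDist = 300000)), 0)
})

test_that("LD pruning leaves no within-window pair above the threshold", {
  set.seed(11)
  g <- matrix(rbinom(30 * 80, 2, 0.5), nrow = 30)
  g[15, ] <- g[14, ]                    # identical pair -> one survives
  gm <- mkGm(g, rep("pop1", 80), pos = as.integer(seq_len(30) * 1000))
  kept <- ldPrune(gm, window = 50, step = 5, r2max = 0.2)
  expect_true(xor(14 %in% kept, 15 %in% kept))
  ## brute-force post-condition: no retained pair with r2 > 0.2
  gk <- genotypes(gm)[kept, ]
  worst <- 0
  for (i in seq_along(kept)[-1]) for (j in seq_len(i - 1)) {
    r2 <- suppressWarnings(stats::cor(gk[i, ], gk[j, ]))^2
    if (!is.na(r2)) worst <- max(worst, r2)
  }
  expect_lte(worst, 0.2)
})

test_that("genotype panels round-trip through minimal VCF text", {
  skip_if_not_installed("vcfR")
  gm <- simulatePopulation(c(chr1 = 1000000L),
                           populationModel(c(10L, 10L), F = 0.1,
                                           nSites = 50L,
                                           missingRate = 0.05), seed = 8L)
  v <- tempfile(fileext = ".vcf"); pm <- tempfile(fileext = ".tsv")
  writeGenotypeVcf(gm, v, pm)
  back <- readGenotypeVcf(v, pm)
  expect_equal(unname(genotypes(back)), unname(genotypes(gm)))
  expect_equal(as.character(populations(back)), as.character(populations(gm)))
  expect_equal(GenomicRanges::start(SummarizedExperiment::rowRanges(back)),
               GenomicRanges::start(SummarizedExperiment::rowRanges(gm)))
})
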