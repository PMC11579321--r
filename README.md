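# T2Tkit

Toolkit for curating and evaluating telomere-to-telomere (T2T) genome
assemblies of acrocentric mammalian genomes, written for assembly engineers
and population geneticists who need the bespoke stages of a T2T project as
tested, reusable R functions rather than one-off scripts.

A gap-free chromosome assembly is finished and judged by a small set of
recurring computations, and T2Tkit implements each of them:

* **Canonical k-mer statistics** — counting (`countKmers()`), parental
  hapmer extraction and trio read binning (`extractHapmers()`,
  `binReads()`), Merqury-style consensus quality
  `QV = -10·log10(1 − (1 − absent/total)^(1/k))` (`estimateQV()`), rare
  k-mers, and the minimum-unique-k-mer (MUK) repetitiveness track per
  100-kb window (`mukTrack()`).
* **Assembly finishing** — triage of gap-spanning reads into three anchor
  kinds (identity ≥ 95%, flank coverage ≥ 90%, QV ≥ 20), a rare-k-mer-guarded
  overlap graph whose best path (longest accumulated rare-k-mer support)
  fills the gap (`classifyGapReads()`, `buildOverlapGraph()`, `fillGap()`),
  junction verification (> 5 spanning reads at MAPQ ≥ 60), telomere
  detection (> 10 tandem TTAGGG/CCCTAA copies at a chromosome end) and end
  patching, low-quality region classification and pileup polishing.
* **Repeat landscape** — centromeric satellite monomer discovery by greedy
  circular k-mer extension (recovering the caprine SatI/SatII/SatIII unit
  lengths of 816/702/22 bp), satellite annotation, sequence-complexity and
  windowed-depth tracks, multi-evidence centromere calls, pairwise 10-kb
  identity heatmaps, and segmental-duplication detection under the four
  classic filters (≥ 1 kb, > 90% identity, ≤ 50% gapped, ≤ 70% satellite).
* **Assembly comparison** — synteny chaining with inversion calls, and
  previously-unresolved-region (PUR) / newly-assembled-region (NAR)
  detection from one-to-one filtered alignments.
* **Population scans** — GATK-style hard site filters, MAF/missingness
  filtering, multi-caller SV merging (1000-bp bin, ≥ 50 bp), windowed
  Weir–Cockerham F<sub>ST</sub> (50-kb windows, 10-kb step), nucleotide
  diversity π and π-ratio, top-1% sweep regions, LD decay and LD pruning.
* **Synthetic data with full ground truth** (`makeGenome()`, `makeTrio()`,
  `simulateReads()`, `plantGaps()`, `simulatePopulation()`,
  `simulateSvCallsets()`) so that the entire pipeline is testable end to
  end without downloading anything: telomere-capped acrocentric
  chromosomes, satellite arrays, planted duplications and gaps, trios with
  known haplotype origin, reads with tunable error, and a two-population
  Balding–Nichols panel with planted sweeps.

Sequence containers are Biostrings `DNAStringSet`s, intervals are
`GRanges`, and genotype panels are `SummarizedExperiment`-based
`GenotypeMatrix` objects; alignments follow PAF semantics through thin
minimap2/Rsamtools wrappers.

## Worked example

```r
library(T2Tkit)

spec <- genomeSpec(
  chromLengths = c(chr1 = 300000L, chr2 = 200000L),
  telomereCopies = 12L,
  centromeres = data.frame(chrom = "chr1", start = 20000,
                           monomerLength = 816, copies = 120,
                           divergence = 0.02),
  seed = 7L)
genome <- makeGenome(spec)
genome
#> SyntheticGenome: 2 chromosomes, 500000 bp; 5 truth features ( centromere/telomere )

detectTelomeres(genome)
#>   chrom end  motif copies  start   stop length distToEnd
#> 1  chr1  3p CCCTAA     12 299929 300000     72         0
#> 2  chr1  5p TTAGGG     12      1     72     72         0
#> 3  chr2  3p CCCTAA     12 199929 200000     72         0
#> 4  chr2  5p TTAGGG     12      1     72     72         0

units <- discoverSatelliteUnits(chromSeqs(genome), k = 21, minCount = 20)
units[, c("family", "length", "support")]
#>   family length support
#> 1  unit1    816      94
#> 2  unit2      6      36

reads <- simulateReads(genome, readProfile(depth = 30), seed = 8L)
estimateQV(chromSeqs(genome), countKmers(reads, 21))
#> QVReport: genome-wide QV 99 (error 0; 0/499960 assembly k-mers absent from reads)
```

Both ends of both chromosomes carry exactly the planted 72-bp (12-copy)
telomere arrays; monomer discovery recovers the planted 816-bp satellite
unit exactly (`unit2`, length 6, is the telomeric repeat itself, which is
also a tandem unit); and with error-free 30× reads no assembly k-mer is
missing from the read set, so the QV reports at its cap — plant
substitutions into the assembly and the QV drops accordingly.

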