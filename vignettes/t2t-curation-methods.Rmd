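---
title: "Methods: curating a telomere-to-telomere assembly with T2Tkit"
author: "T2Tkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curating a telomere-to-telomere assembly with T2Tkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

T2Tkit reimplements, as tested reusable functions, the bespoke computational
stages used to finish and evaluate a telomere-to-telomere (T2T) assembly of
an acrocentric mammalian genome (the motivating system is the domestic goat,
whose 29 autosomes and X chromosome are all acrocentric), and the
population-genetic scan that such an assembly enables. This vignette is the
package's own account of the models, the parameters that matter, the
numerical choices, and what the synthetic-data tests do and do not show.

## The synthetic genome and why it exists

None of the toolkit's algorithms can be meaningfully tested on real data
inside a test suite: the inputs are tens of gigabases of reads and the truth
is unknown. The `simforge` layer (`genomeSpec()`, `makeGenome()` and
friends) therefore generates every input the other stages need, with exact
ground truth:

* **Chromosome backbones** are i.i.d. uniform random DNA. Real genomes have
  GC structure, transposon landscapes and mutation-rate variation; random
  backbones have none of these, so passing tests demonstrate algorithmic
  correctness on unambiguous sequence, not robustness to every genomic
  idiosyncrasy.
* **Telomeres** are exact tandem copies of the vertebrate telomerase motif
  (`TTAGGG` planted at the 5' end, its reverse complement `CCCTAA` at the
  3' end), 12 copies per end by default — enough to clear the detector's
  "strictly more than 10 copies" rule with margin while staying tiny.
  Interruptions are off by default.
* **Centromeric satellite arrays** use one random monomer per family,
  with family lengths of 816, 702 and 22 bp — the unit lengths of the three
  caprine centromeric satellite families (SatI/SatII/SatIII). Divergence is
  applied per copy as i.i.d. substitutions, with no indels, which keeps the
  planted monomer length exactly checkable.
* **Segmental duplications** copy a source interval to a target position
  with i.i.d. substitution divergence (again no indels, so the copies stay
  on one alignment diagonal).
* **Gaps** (`plantGaps()`) replace an interval with an equal-length N-run
  and withhold the removed sequence for round-trip scoring.
* **Trios** (`makeTrio()`) give each of the four parental haplotypes an
  independent Binomial(L, het) set of SNVs; the child is byte-identical to
  one paternal and one maternal haplotype. The default heterozygosity of
  1e-3/bp is a typical mammalian value.
* **Reads** (`simulateReads()`) have normal lengths (long-read default mean
  18,950 bp, matching a typical HiFi N50 of 18.95 kb), uniform fragment
  starts clipped at chromosome ends (so ends are covered), random strands,
  and optional substitution and single-base-indel errors. There is no
  homopolymer-aware or platform-specific error model.
* **Populations** (`simulatePopulation()`) follow the Balding–Nichols
  model: one ancestral frequency per site, per-population frequencies drawn
  from Beta(p(1-F)/F, (1-p)(1-F)/F), genotypes binomial. The expected
  between-population FST equals the drift parameter F, giving an analytic
  target for estimator recovery. Sweeps multiply a target population's
  per-site expected heterozygosity by a factor inside a known interval —
  a deliberate stand-in for hitchhiking dynamics that trades realism for an
  exact truth interval. The source study contrasted wild bezoars with
  domestic goats; it states no noise model, so Balding–Nichols is this
  package's documented choice, not the study's.

Determinism is a hard requirement throughout: every generator seeds R's RNG
locally (restoring the caller's RNG state), so identical spec + seed gives
byte-identical output.

## k-mer statistics

All k-mer work is canonical: a k-mer is represented by the lexicographic
minimum of itself and its reverse complement, matching standard k-mer
tooling; k must be odd because reverse-complement palindromes (possible only
at even k) make canonicalization ambiguous. Windows containing non-ACGT
characters are skipped entirely. Counting is done in C++ (2-bit packing for
k <= 31, string keys above that, up to the k = 151 used for satellite
discovery).

**Hapmers and trio binning.** A paternal hapmer is a k-mer present in the
father's table, absent from the mother's, with child depth strictly between
`dmin = 3` and `dmax` (default: the child's mean table depth, mirroring the
classic bound of "> 3 and < the genome-wide average depth", 120x in the
motivating dataset). Whether the upper bound should scale with depth is not
settled anywhere; scaling with the observed mean is this package's choice
and it is overridable. Reads are assigned to the side with strictly more
hapmer hits; ties, including 0–0, are ambiguous. k = 21 is the conventional
trio-binning size.

**QV.** The Merqury-style estimator: with `absent` of the assembly's `total`
k-mers missing from the read table, per-base survival is
P = (1 - absent/total)^(1/k), error E = 1 - P, QV = -10 log10 E. Zero absent
k-mers report the cap (99), a finite-reporting convention. The estimator is
warned-about below 10x read depth, where read dropout masquerades as
assembly error.

**Rare k-mers** are those with count strictly below the table's mean depth
(k = 23 by convention for gap filling); in a uniformly covered unique genome
roughly half of all k-mers are rare, while satellite k-mers are far above
the mean and never rare — exactly the property the gap filler exploits.

**MUK** (minimum unique k-mer length) per 100-kb window is the smallest
L in [21, 100000] such that some length-L substring *starting inside* the
window occurs exactly once genome-wide counting both strands; windows with
no unique substring report the cap. "Starting in" rather than "contained
in" keeps windows at repeat edges meaningful. The implementation runs a
per-window binary search over L with one genome-wide canonical-hash
counting pass per candidate L; the binary search assumes uniqueness is
monotone in L, which holds except for degenerate windows at the extreme
chromosome tail (a superstring of a unique string is unique whenever it
exists). Tests verify equality with an exhaustive linear scan.

## Assembly finishing

**Gap-read triage.** Reads aligned (PAF) to the gapped assembly are
classified against each N-run: kind-1 reads reach a gap boundary (within
100 bp) at identity >= 0.95, flank-side coverage >= 0.90 and read QV >= 20;
kind-2 reads align only roughly to the +/-50-kb neighborhood; kind-3 reads
align nowhere and may come from the gap interior. "Coverage" is read here as
the aligned fraction of the read's flank-side portion — the portion from the
read end facing the flank up to the boundary — because a gap-crossing read
can never align its gap half; the interpretation is configurable. Read QV
uses FASTQ qualities when supplied and an identity-derived proxy otherwise.

**Overlap graph and filling.** Dovetail suffix–prefix overlaps between
oriented reads (from all-vs-all minimap2) become directed edges only when
the overlap contains at least one rare k-mer — the guard against false
overlaps between repeat copies. Each edge also records where novel sequence
begins on the target read, so a chosen path can be stitched exactly. A
single kind-1 read anchored on both sides short-circuits the search;
otherwise left-to-right paths are enumerated (bounded DFS, 10,000
expansions, then greedy), the path maximizing accumulated rare-k-mer support
wins, and ties break by higher mean identity then lexicographic node name
for determinism. Path interiors are restricted to gap-associated reads
(kind-1 and kind-3): well-anchored flank reads may sit in the graph but
cannot form the middle of a fill path, which keeps the search from drifting
along the flanks. Patch consensus is simple stitching at the recorded
overlap cuts (with error-free or HiFi-grade reads the stitched patch is
already exact); a full partial-order consensus is out of scope. Flanks
outside the N-run are never modified.

**Junction verification** passes when strictly more than 5 essentially
unclipped reads span the position +/-1 kb at MAPQ >= 60. The classic rule is
stated as "MAPQ > 60", which is unsatisfiable under the 60 cap that common
long-read aligners apply; >= 60 is the implemented reading.

**Telomeres.** Both `TTAGGG` and `CCCTAA` are searched at both ends of every
sequence (the motivating study reports TTAGGG at the 5' end and CCCTAA at
the 3' end — the reverse of the usual vertebrate forward-strand convention —
so the detector accepts either and records what it saw). Copies are exact
tandem 6-mers; a single interruption of at most 6 bp joins two runs without
resetting the count. A call needs strictly more than 10 copies within 10 kb
of an end, and an array inside both end windows (short sequences) is
assigned to its nearer end. End patching places a telomere-bearing contig
onto a terminal 1-Mb window when exact-probe offsets agree, overlap is
>= 10 kb at >= 99% identity, and the contig extends outward with its
telomere facing out; ambiguous multi-end placements are reported and left
alone.

**Polishing.** Windows (1 kb) are low-quality when median MAPQ <= 1, when
both-end-clipped reads pile up, or when fewer than 3 reads cover them;
adjacent same-label windows merge into a partition of the chromosome.
Pileup polishing (via samtools-backed pileups) applies substitution-only
majority consensus at columns with depth >= 3 and majority fraction >= 0.6,
optionally restricted to the low-quality segments first, mirroring the
staged low-quality-first pipeline; indel polishing is out of scope.

## Repeat landscape

**Satellite monomer discovery** is a greedy circular extension over the
k-mer table: the highest-count unconsumed k-mer seeds a walk that repeatedly
appends the most frequent successor base (ties break in A<C<G<T order);
when the walk returns to its seed, the traversed bases are one monomer.
Consumed k-mers are removed and the next family is seeded. The published
tool this stands in for (SRF) does not document its internals, so this
reimplementation is validated purely by monomer-recovery tests: planted
monomers of 816/702/22 bp are recovered at exactly their planted length for
divergence <= 5%, rotation- and strand-invariantly (units are reported in
canonical rotation — the lexicographic minimum over rotations of both
strands). The conventional table parameters are k = 151 with a count floor
of 20; at percent-level divergence the package's tests use k = 21, where
exact k-mer survival across divergent copies is high enough for desk-scale
arrays (0.98^151 is ~0.05, so k = 151 needs several hundred copies to seed).

**Annotation** locates monomer occurrences on both strands with a
substitution budget from the identity floor (0.80) and merges consecutive
hits into arrays. **Complexity** is the mean over substring lengths 1..12 of
(distinct substrings observed) / (maximum possible) per 10-kb window; the
cited linguistic-complexity tool publishes no formula, so this
distinct-substring ratio is the package's documented choice. **Identity
heatmaps** align whole 10-kb windows globally (best of both strands),
identity = matches / alignment columns; global rather than local alignment
keeps unrelated windows at the random baseline instead of scoring short
chance matches.

**Centromere calls** overlay four window tracks — ChIP depth (5-kb
windows), methylation (20 kb), satellite density (10 kb), complexity
(10 kb) — with thresholds 2x genome median, 1.5x median, >= 50% and <= the
10th percentile respectively. The motivating study combines this evidence
qualitatively; the numeric thresholds are this package's calibration. A
window seeds a candidate only when a second evidence type passes at an
overlapping window (pairwise corroboration), candidates merge within
100 kb, calls need >= 2 evidence types, and at most one call per chromosome
survives by default (acrocentric model). Boundaries follow the evidence
windows, i.e. effectively the satellite extent; whether published
centromere boundaries follow satellite or ChIP extent is unstated, and
satellite extent is the choice here.

**Segmental duplications** come from exact 15-mer seed matches (seeds above
an occurrence cap are skipped, which drops satellite-saturated seeds),
chained by diagonal, aligned, and filtered by the four classic criteria:
aligned length >= 1 kb, identity > 90%, gapped fraction <= 50%, satellite
fraction <= 70% (computed from the package's own satellite annotation,
standing in for an external repeat masker). Substitution-only planted
duplications stay on one diagonal, so diagonal chaining is exact here;
indel-shifted duplications would need banded chaining, a documented
limitation.

## Assembly comparison

Synteny chaining groups PAF records by (query, target, orientation) and
chains records within 50 kb on both axes; reverse-orientation blocks
>= 100 kb are inversions. PUR (previously unresolved region) detection takes
the new assembly's bases not covered by any one-to-one filtered alignment
(>= 10 kb, best-reciprocal by greedy overlap exclusion at 50%) to the old
chromosomes, merged, >= 5 kb (the floor avoids crediting alignment jitter);
NAR additionally requires no coverage by old unplaced contigs, so NAR is
contained in PUR by construction. The published PUR pipeline's exact
aligner parameters are uncited; the defaults here are explicit
configuration, not an inference of that study's settings.

## Population scans

Hard site filters follow the classic GATK thresholds (QD < 2, QUAL < 30,
SOR > 3, FS > 60, MQ < 40, MQRankSum < -12.5, ReadPosRankSum < -8); absent
metrics never trigger. Matrix filtering retains sites with <= 10%
missingness, MAF >= 0.05 and two alleles. Multi-caller SV merging collapses
same-type calls within a 1000-bp bin and 50% reciprocal length overlap
(the reciprocal rule is this package's choice; the cited merger does not
restate its internals), keeps >= 50-bp calls (the literature prints both
"> 50 bp" and ">= 50 bp"; >= 50 is implemented), and is idempotent and
order-invariant because input is canonically sorted before clustering.

FST uses the Weir–Cockerham (1984) per-site variance components accumulated
over 50-kb windows with a 10-kb step (window value = sum(a) / sum(a+b+c)),
matching the behavior of the standard windowed implementations; the Hudson
ratio-of-sums estimator is provided as the independent cross-check. Sites
where either population has fewer than two non-missing genotypes are
skipped; missing genotypes are excluded per site. Nucleotide diversity per
window is the unbiased per-site heterozygosity sum divided by the *full*
window length (the cited tool's convention; unobserved positions count as
monomorphic). The pi ratio flags windows with zero denominator as undefined
and excludes them from ranking. Top-percentile selection cuts at the
ceiling(n * pct/100)-th largest value with ties included (all-tie inputs
warn), merges overlapping/adjacent windows, and works genome-wide (whether
published top-1% cuts are genome-wide or per-chromosome is unstated;
genome-wide is implemented). LD decay averages genotype r-squared in
distance bins up to 300 kb; LD pruning is the classic 50-site/5-step/0.2
sliding window, removing the lower-MAF member of each offending pair.

## Problem sizes used by the test suite

The tests run the whole pipeline at desk scale, chosen once for statistical
resolution: trio binning on a 2-Mb genome at 20x (about 40 heterozygous
sites per 20-kb read — accuracy is effectively limited only by hapmer
correctness); QV recovery on a 10-Mb genome at 30x so that the rarest
planted error rate (1e-5, about 100 errors) is measured within one QV unit
at better than two standard deviations; gap filling on a 50-kb gap with 30x
20-kb reads; FST recovery on 5000 sites with 50 diploids per population
(standard error of FST well under the 0.03 acceptance band); and 20 seeded
sweep replicates of 2500 sites over 5 Mb with a 500-kb sweep at diversity
factor 0.1. Random backbones make repeat-induced ambiguity essentially
impossible outside the planted features; that is the point of the design —
failures indicate algorithmic defects, not hard inputs.

## Known limitations

* Read simulation has no homopolymer or platform-specific error structure;
  ONT-like error profiles are out of scope.
* The sweep model is multiplicative diversity reduction, not hitchhiking;
  no recombination or coalescent structure is simulated.
* Gap-fill consensus is stitching, not partial-order alignment; with noisy
  reads the patch inherits read errors at roughly the read error rate
  (polishing afterwards is the intended remedy).
* SD chaining assumes substitution-dominated divergence (single diagonal).
* In-memory k-mer tables are practical to the hundreds of megabases;
  disk-backed counting is not provided.
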