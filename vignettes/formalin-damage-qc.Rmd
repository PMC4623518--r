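---
title: "Profiling and trimming formalin damage in historical sequencing libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling and trimming formalin damage in historical sequencing libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(formalinQC)
```

## The problem

DNA recovered from formalin-fixed, fluid-preserved museum specimens (and
other historical material) is short, scarce and chemically modified.
When such libraries are sequenced and aligned to a reference, base
misincorporations show up as reference mismatches concentrated at the read
ends. Unlike the classic signature of non-formalin historical DNA — C→T
inflation at 5' ends and G→T at 3' ends from cytosine deamination —
formalin-type damage elevates essentially *all twelve* substitution types
at both ends, usually more sharply at 3'. Because the damaged bases are
confined to the read extremities, a data-driven *hard trim* (removing a
fixed number of bases per end, regardless of quality scores) recovers
usable data; ordinary quality trimming does not, since damaged bases carry
normal quality scores.

formalinQC implements the computational path of that recovery: per-offset
mismatch profiling, an explicit flatness criterion that turns "trim until
the profile is flat" into a reproducible rule, the surrounding read
cleanup (duplicate removal, quality filtering, overlap merging), and the
reference-based summaries used to judge the outcome (empirical error
rate, coverage breadth/depth, majority consensus with SNP counts). A
damage-aware read simulator with truth alignments makes every stage
testable without an aligner or external data.

## Mismatch profiles

For every aligned (M/=/X) column of a primary alignment with MAPQ ≥ 20 we
compare read base to reference base. Columns in which either base is N are
excluded from both numerator and denominator; insertions, deletions and
clips contribute nothing but advance the cursors. Each mismatch is one of
the 12 ordered types ref→read over {A,C,G,T}.

Observations are expressed in **sequenced-read orientation**: for a
reverse-strand alignment both bases are complemented and the 5' offset is
flipped (`offset5 = read_len − 1 − column`), so `offset5` is always the
0-based distance from the sequenced 5' end and `offset5 + offset3 =
read_len − 1`. We adopt read space because end-anchored damage is a
property of the molecule's ends as sequenced; in reference space the same
event would smear across both ends depending on alignment strand. This
convention matters when comparing numbers with tools that profile in
reference space.

A `MismatchProfile` holds, per mate and per end, the 12 × (maxOffset + 1)
count table and the per-offset denominators (comparable columns), with
frequencies derived as count/denominator.

```{r, eval = FALSE}
aln <- readAlignments("library.sam", refset)
p1 <- mismatchProfile(aln, refset, mate = "R1")
exportProfile(p1, "profile_R1.tsv")
```

## The flatness criterion and trim detection

"Trim until the frequencies of all types are relatively constant and
similar" needs a definition. For each (mate, end) independently:

1. A **baseline window** of offsets deep inside the read (default
   `[maxOffset/2, maxOffset]`, i.e. 25–50 at the default `maxOffset = 50`)
   provides, for each type *t*, a robust baseline: median *m~t~* and MAD
   *s~t~*; the pooled (all-type) frequency gets the same treatment.
2. An offset *i* within the scan window (`maxTrim = 40` bases) is
   **flagged** when its pooled frequency, or any single type's frequency,
   exceeds its own baseline median by `max(kMad · 1.4826 · MAD, absFloor)`
   with `kMad = 3` and `absFloor = 0.002`.
3. The trim length is one past the largest flagged offset (0 if none).
   Contiguity is deliberately not required: a damage curve may dip below
   threshold and re-exceed it nearer the end.

Both the pooled and the per-type screens are needed. A deamination-style
process loads one type heavily and is caught per type; formalin-style
damage spreads an amplitude *a* over all 12 types, so each type carries
only ≈ *a*/12 — potentially below any sensible per-type floor — while the
pooled frequency crosses `absFloor` exactly where the total excess does.
For an exponential damage profile `a·exp(−i/λ)` over a baseline error rate
the pooled rule flags offsets up to approximately `λ·ln(a/absFloor)`,
which is the analytic trim point the package's tests check against.

Parameter notes, all user-settable via `flatnessParams()`:

* `absFloor` (frequency units, default 0.002): the smallest excess over
  baseline considered biologically meaningful. It also bounds what remains
  after trimming — see *Limitations*.
* `kMad` (robust z units, default 3): controls false flags when MAD noise
  exceeds the floor; per-type baselines are kept separate because
  transition baselines exceed transversion baselines even in undamaged
  data.
* `minDenom` (columns, default 500): offsets with fewer comparable columns
  are neither flagged nor used for baselines, so sparsely covered offsets
  cannot dominate via noise.
* `maxTrim` (bases, default 40, must lie within the profiled offsets):
  caps runaway trimming. Libraries whose profiles are uneven everywhere —
  the failure mode of badly degraded specimens — should fail loudly
  (`iterateTrim(..., converged = FALSE)`), not silently trim whole reads.

`iterateTrim()` repeats profile → detect until flat (default 5 rounds),
**masking** the already-trimmed offsets of the original alignments and
shifting the remaining offsets, rather than re-aligning trimmed reads.
Masking is deterministic and aligner-free; the difference from true
re-alignment is that masked reads keep their original mapping positions.
When exact re-alignment behaviour is wanted, align the trimmed reads
externally and feed the new SAM through the same functions.

## Read cleanup

`applyTrim()` removes the spec'd bases per mate and end and drops pairs in
which either mate falls under `minLen = 30`. `removeDuplicates()` keys on
the concatenated pair sequence (qualities and positions ignored), keeps
first occurrences, and reports the duplicate fraction **of pairs** — when
comparing against duplicate rates quoted per read, note the denominator.
`qualityFilter()` drops pairs whose mean Phred falls below 20 (a mean
exactly at the threshold is kept) or whose N fraction exceeds 10%.
`mergeOverlaps()` reverse-complements R2, scans candidate overlaps from
longest to shortest, and accepts the first with ≥ 11 bases and ≤ 10%
disagreement; within the overlap the higher-quality base wins (R1 on
ties) and the quality is the per-column maximum. Merged reads are emitted
separately (`mate = "merged"`) because downstream paired and unpaired data
are handled separately. Adapter trimming is intentionally out of scope:
run a dedicated adapter trimmer first.

## Reference-based summaries

* **Empirical error rate**: mismatched aligned bases over comparable
  aligned bases in a region, same column semantics as the profiles.
* **Coverage**: per-bin read counts assign each alignment to exactly one
  bin by its leftmost aligned base (so bin counts sum to the read count);
  depth uses full reference spans (M/=/X/D); breadth is the fraction of
  positions with depth ≥ 1.
* **Consensus**: per-position base counts from aligned columns (deletions
  give no evidence, insertions ignored). A site is called when depth ≥ 3
  and the majority base reaches 75%; anything else — including exact ties —
  is N rather than the reference base, to avoid reference bias in SNP
  counts. "High-quality SNP" is thus operationalised as a called site that
  differs from the reference, and dissimilarity is SNPs per called
  (non-N) site. Both thresholds are arguments.
* **GC content** excludes ambiguity codes from the denominator; the
  length filter reports the standard N50 over the retained contigs.

## The simulator

`simulateLibrary()` emulates the phenomenology this package exists to
handle, at desk scale:

* **Fragments**: a two-component lognormal length mixture (medians 120 bp
  and 240 bp, σ~log~ = 0.25, equal weights) mimicking the bimodal sizing
  traces of degraded libraries; uniform position and strand; lengths
  clamped to ≥ 35 bp. 100 bp reads from both ends; a fragment shorter than
  the read length yields reads equal to the fragment (no adapter
  read-through is simulated).
* **Damage**: per read end, offset *i* is hit with probability
  `a·exp(−i/λ)`; the substituting base is drawn from the model's type
  weights conditioned on the true base (uniform weights → each of the 3
  alternatives at (a + e0)/3, hence each *type* at (a + e0)/12 under a
  50% GC reference — an expectation the tests verify by enumeration, not
  the a/11 one might guess from "12 types, one excluded"). `adna` mode
  moves the 5' mass to C→T and the 3' mass to G→T.
* **Errors**: i.i.d. baseline rate `e0` to a uniformly chosen different
  base, applied after damage; a truth record exists for every position
  whose emitted base differs from the template.
* **Duplicates**: with probability `dupRate` an emitted pair is an *exact
  copy* of a uniformly chosen, previously emitted original pair. Copies
  share the template's damage and errors — that is what makes PCR
  duplicates exact sequence duplicates, removable before alignment, and it
  keeps the measured duplicate fraction an unbiased estimate of
  `dupRate`. Duplicates are never drawn from other duplicates:
  resampling from all previous pairs is a preferential-attachment process
  whose power-law copy numbers would put large single-fragment spikes into
  the profiles.
* **Sample divergence**: optional substitutions applied to the sequencing
  template before fragmentation, for consensus/SNP recovery studies.
* **Truth**: every read's error-free coordinate alignment (all-M CIGAR) is
  emitted alongside, so no aligner is ever needed; qualities are constant
  Q35.

What the simulator does **not** emulate — and therefore what passing tests
do not establish about real data: adapter read-through, quality-dependent
and indel errors, mappability and repeat structure (alignments are placed
by construction, so there is no mismapping), contaminant reads, GC-biased
coverage, and chimeric fragments. Results on real libraries additionally
depend on the aligner's handling of damaged ends.

Presets bundle the regimes used throughout the tests: `good_specimen`
(64% duplication, a = 0.02, λ = 8, e0 = 0.002), `failed_specimen` (97.5%
duplication, a = 0.08, λ = 15, e0 = 0.004) and `undamaged`.

## Numerical and design choices

* Coordinates are 1-based inclusive throughout (the R/Bioconductor
  convention); read-end offsets are 0-based distances, matching how
  profile plots are usually drawn.
* The reference sequence, when supplied, is authoritative for mismatch
  calls; MD tags are used to reconstruct reference bases only when no
  reference is available, and an MD/CIGAR inconsistency is an error there.
* Duplicate removal keeps the *first* occurrence (order-stable);
  merge ties go to R1; consensus ties go to N.
* Degenerate inputs: an empty alignment set gives an all-zero profile and
  a zero coverage table; a region with no aligned bases has no defined
  error rate (error); an all-N sequence set has no defined GC (error);
  an empty post-filter contig set reports N50 = 0 with a warning.
* Test and acceptance runs use 2,000–50,000 read pairs on 17 kb–1 Mb
  references — sizes chosen so that every statistical check has binomial
  noise well below its tolerance while the whole suite stays fast.

## Limitations

* **Residual damage below the floor.** Trimming stops where the pooled
  excess crosses `absFloor`, so each read retains an exponential tail of
  damage of total mass ≈ `absFloor/(1 − e^{−1/λ})` per end. At the default
  floor and λ = 8 that is ≈ 0.017 mismatches per end, i.e. roughly
  0.0005–0.0006 extra per-base error over a ~60 bp trimmed read — a
  post-trim error rate ~25–30% above the sequencing baseline rather than
  at it. Tightening `absFloor` trims further at the cost of data loss;
  the package reports both pre- and post-trim rates so the trade-off is
  visible.
* **Duplication over-dispersion.** With heavy PCR duplication the
  per-offset mismatch counts are over-dispersed (copies share damage), so
  profiles from small, highly duplicated libraries are spiky; detect trims
  after duplicate removal, or at ≥ tens of thousands of pairs, for stable
  results.
* **Masking is not re-alignment.** Reads whose damaged ends drove their
  original placement keep that placement under masking; the escape hatch
  is an external re-alignment of trimmed reads.
* The consensus caller is haploid-style (majority base); it is intended
  for organellar genomes and does not genotype heterozygous sites.
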