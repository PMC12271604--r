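---
title: "Benchmarking structural variant callsets with svcompare"
author: "svcompare authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking structural variant callsets with svcompare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Two structural variant (SV) callers rarely describe the same event the same
way. Alignment ambiguity, repeat structure and caller heuristics shift
breakpoints, change reported lengths, and -- most damagingly for
benchmarking -- sometimes fragment one large insertion or deletion into
several adjacent smaller calls. A benchmarking tool that only compares
individual records then reports false positives (the fragments) *and* a
false negative (the missed large variant) for what is really a correct
detection in a different representation.

`svcompare` classifies calls against a benchmark VCF as **TP** (benchmark
variant recovered), **FP** (call with no counterpart), **FN** (benchmark
variant missed) and **LP** (*latent positive*: a call that fails to match
alone, but whose merge with adjacent calls reconstructs a benchmark
variant; the reconstructed benchmark variant counts as TP). Matching uses
five criteria; a second local joint-analysis pass recovers the
split-representation cases.

## Matching model

A record is `(chrom, S, E, L, type, sequence)` with type in
{INS, DEL, DUP, INV}. Lengths are normalized positive; ends are rederived
from the length (`E = S + L - 1` for spanned types, `E = S` for
insertions) because INFO `END` values are unreliable in the wild. For a
query/benchmark pair the five criteria are:

1. **Type**: identical types; in *loose* mode INS and DUP are compatible
   (a tandem duplication is an insertion of the duplicated unit).
2. **Reference distance**: `|S1 - S2| <= extend_len(max(L1, L2))` with
   `extend_len(L) = 200` bp for `L <= 100` bp and 1 kbp above. The larger
   variant of the pair governs, since it is the one whose placement is
   more uncertain.
3. **Overlap**: spans extended per side -- spanned types by
   `extend_len(L)`, insertions by a fixed 100 bp (they have no reference
   span) -- must intersect. (We use the standard intersection inequality
   `max(starts) <= min(ends)`; stated the other way round, identical
   variants would be disjoint.)
4. **Size similarity**: `min(L1, L2) / max(L1, L2) >= 0.7` by default.
5. **Sequence similarity** (resolved alleles only): see below,
   `>= 0.7` by default. Symbolic alleles (`<DUP>`, `<INV>`) have no
   computable sequence score; the criterion is then vacuous and the match
   is decided by the other four.

### Relief-factor sequence similarity

Variant sequences (inserted bases for INS, deleted bases for DEL) are
aligned globally (Needleman-Wunsch; match +1, mismatch -1, linear gap -2
by default, all configurable). From the alignment we take `M`, the
matching columns, and `G`, the gap characters lying in maximal gap runs of
length >= 3 (counted per sequence). The score is

    score = (M + RF * G) / alignment_length,

with relief factor `RF` in [0, 1] (default 0.5). Long gap runs are
alignment artifacts more often than biological signal -- e.g. the length
difference between two honest representations of one event -- so they are
partially credited rather than fully penalized. `RF = 0` reduces to the
plain match fraction; raising `RF` never lowers a score.

Two scores are computed and the maximum taken: the raw variant sequences
(**X**), and the sequences embedded in a shared reference context spanning
from the upstream-most start to the downstream-most reference-span end of
the pair (**A**). The context score rescues placement differences: the
same insertion reported at two positions inside a tandem repeat spells the
same haplotype, and only the contextual alignment can see that. For
deletion pairs the context construction (left context + deleted bases +
right context) reconstructs the reference interval on both sides, so the A
score is ~1 by construction and deletion matching is effectively governed
by the four other criteria -- a direct consequence of deriving the deleted
sequence from the REF column, and consistent with deletions carrying
reference, not novel, sequence.

Ties between co-optimal alignments are broken deterministically (diagonal,
then gap-in-second, then gap-in-first), and the two sequences are put into
canonical order before aligning so the score is exactly symmetric in its
arguments.

### Large variants: minimizer anchoring

Full dynamic programming on two >10 kbp sequences is slow and
memory-hungry. When both sequences exceed the threshold, they are sketched
with minimizers (k = 15, window w = 10 k-mers; splitmix64 hash of the
2-bit encoding, seed 0, truncated to 53 bits so sketches are reproducible
across platforms). Hash values occurring uniquely in both sketches become
anchor candidates; a colinear chain is selected by longest strictly
increasing subsequence of second-sequence offsets (leftmost-tie patience
sorting), and overlapping anchors are trimmed to disjoint k-length spans.
Anchors count as exact matches; inter-anchor segments are aligned with the
same NW scoring; the merged alignment is scored with the same relief
formula. On similar sequences (the intended regime) this tracks the
full-matrix score closely -- the suite checks agreement within 0.05 on
random 10-12 kbp pairs at >= 90% identity, 50 pairs per run.

If no colinear anchor survives, the pair falls back to direct alignment
when the DP matrix stays under 5x10^7 cells, and otherwise scores 0 with a
`no_anchor` flag -- dissimilar sequences of that size would not pass the
0.7 threshold anyway. A segment pair that would individually exceed
4x10^7 cells (possible only for pathological anchor layouts) is scored as
an unaligned block rather than aligned.

## Search and allele-aware selection

The benchmark set is split per chromosome and position-sorted. Stage 1
retrieves benchmark records within
`w0 = clamp(chrom_length * 1e-5, 200 bp, 1 kbp)` of the query start --
honoring both the "fraction of the chromosome" and the "initial 200 bp"
descriptions of the search space across human chromosome sizes. Benchmark
records longer than 100 bp are additionally retrieved within the 1 kbp
expanded window: the distance criterion is governed by the larger variant,
so such records can legitimately match a nearby short query, and the index
must not hide candidates that the criteria would accept (the suite checks
the accelerated matcher against an exhaustive scan). If stage 1 is empty
and the query is >= 100 bp, stage 2 widens to 1 kbp and filters by type
compatibility and a query/benchmark size ratio in [0.7, 1.2].

Among fully passing candidates the highest sequence similarity wins
(symbolic pairs rank by size similarity), ties broken by smaller |d|, then
lower benchmark position. Each benchmark record is consumed by at most one
query and vice versa; the two records of a multi-allelic benchmark site
are distinct records, so two distinct queries can match them -- the
allele-aware behaviour. Queries are processed in genomic order, which
makes consumption, and therefore the whole classification, deterministic
and independent of any parallel execution plan.

## Local joint analysis

After the first pass, residual FP calls are grouped into *superclusters*:
same chromosome, same SV type, single linkage with gaps <= 1 kbp. Within a
cluster, calls with overlapping original coordinates are reduced to the
one with the best first-pass sequence similarity (multi-allelic
protection), and singletons are dropped.

For each first-pass FN benchmark variant, in genomic order, nearby
clusters are tested: contiguous member subsets of 2 up to 6 calls
(breakpoint order; contiguity keeps the enumeration linear, matching how
aligners fragment one event into consecutive pieces) are size-gated
(`size_similarity(combined length, target length) >= 0.7`), then validated
on sequence: the subset's variants are applied to the reference over the
shared region to build the merged haplotype, the target is applied
likewise, and the two haplotypes are aligned and scored as above. The
best-scoring subset at or above 0.7 is accepted; ties resolve to the
smaller span, then leftmost. Members become LP, the target becomes TP, and
each call joins at most one accepted merge. Joint analysis can only move
calls FP to LP and targets FN to TP, so it never decreases TP and never
increases FP or FN.

The upstream description of this step also mentions filtering merge
candidates by raw read signals from BAM input; no algorithm is specified
for it, and `svcompare` is a VCF-level tool, so clustering operates on the
VCF records alone.

## Metrics

With benchmark-side TP counting: `recall = TP / (TP + FN)`,
`precision = TP / (TP + FP)`, `F1` their harmonic mean. LP records appear
only in the LP column -- excluded from both the precision numerator and
denominator (this is the convention the published count tables follow).
The mean sequence similarity averages over scored matches, an accepted
merge contributing its single haplotype score once. Results are stratified
into eight size bins (edges 20, 100, 250, 500, 1000, 2500, 5000, 10000,
50000 bp by default; the outer edges and the "< 100 bp" / "> 10 kbp"
extremes are fixed by the method, the interior edges are a reporting
choice and user-overridable). Per accepted match the signed breakpoint
distance `d = S_query - S_benchmark` and span ratio
`r = (E_q - S_q + 1) / (E_b - S_b + 1)` are reported, with headline
fractions `|d| <= 50 bp` and `r` in [0.7, 1.2]. Reports round percentages
half-up to one decimal; the machine-readable JSON keeps full precision.

## The synthetic-data generator

`simulateReference()` / `simulateTruth()` / `perturbCallset()` generate a
reference, a truth set and a perturbed callset with known expected labels.
The perturbations emulate exactly the failure modes the classifier
targets: dropout (expected FN), in-place breakpoint/size jitter within
half the matching tolerances -- shifts clamped to +/-50 bp, sizes within
5% -- (expected TP), splitting into 2-6 adjacent parts carrying the exact
subsequences of the original variant, parts 1-3 bp apart as
alignment-induced splits are (expected LP members + validated target),
decoy calls far from any truth variant (expected FP), and divergent
same-site alleles (expected FP). Truth variants are placed >= 2 kbp apart
so matches are unambiguous by construction.

Split parts carry *exact* subsequences deliberately: merge validation is
then decidable by the similarity threshold alone, isolating engine defects
from biological noise. The generator does not model sequencing error,
genotypes, nested or overlapping truth variants, or the full repeat
structure of real genomes (repeat tracts can be planted, but placement
ambiguity is not labelled), so exact label recovery on fixtures
demonstrates the engine's correctness, not expected accuracy on real data.

## Numerical and design choices

* NW scores default to match +1 / mismatch -1 / gap -2: deterministic,
  hand-checkable, and configurable. The published method does not state a
  scheme.
* `RF` defaults to 0.5 (described as tunable upstream, without a default).
* Gap runs qualify for relief at length >= 3, per the definition of `G`.
* The insertion length is the length of the inserted (ALT) sequence; the
  deletion length is the deleted (REF-carried) span. A stray statement
  that insertion length is the REF length contradicts the size-similarity
  formula and is treated as a typo.
* Degenerate inputs: empty benchmark gives recall 0 with a warning flag;
  unknown chromosomes classify as disjoint with a warning; malformed VCF
  records are skipped and tallied, never fatal.
* Test problem sizes: the oracle-equivalence suite runs 100 random
  instances of up to ~70 records; the anchored-vs-direct agreement suite
  runs 50 pairs of 10-12 kbp; label recovery runs 3 seeds x 25 truth
  variants. These sizes exercise every code path while keeping the suite
  fast.

## Known limitations

* No genotype concordance checking.
* No breakend (BND) or translocation benchmarking; records of other types
  are rejected at ingestion with a tally.
* Sequence similarity is undefined for symbolic alleles; such matches rest
  on the four remaining criteria.
* Benchmark-side records are never merged to match one large call; joint
  analysis merges callset records only.
* The search acceleration assumes sorted per-chromosome access; contigs
  absent from the benchmark produce FP calls without further search.
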