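---
title: "Weighted-MEC haplotype phasing: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted-MEC haplotype phasing: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmecphase)
```

## The problem and the model

A diploid individual carries two haplotypes per chromosome. At a set of m
heterozygous SNPs, each mapped sequencing read reports one of two
(arbitrarily relabelled) alleles, 0 or 1, at the SNPs it covers. The input
is therefore an n × m fragment matrix F over {0, 1, −} with a positive
weight on every active call, encoding how confident the upstream base call
and mapping were — equivalently, the price of overriding that call.

Two reads conflict at a column when both are active there with different
alleles; error-free reads from one haplotype never conflict. Weighted
minimum error correction (wMEC) asks for the cheapest set of call flips
under which the reads can be split into two conflict-free parts. The flip
side of that bipartition is the phasing itself: each part's consensus,
column by column, is one haplotype.

`phase_matrix()` solves wMEC exactly with a column-wise dynamic program
over the bipartitions of the reads *active* at each column. With coverage
c at a column there are 2^c bipartitions, so the method is fixed-parameter
tractable in coverage and indifferent to read length — the regime long-read
data lives in. The recurrence adds, to each bipartition's local correction
cost (each part flipped to its cheaper uniform allele), the cheapest cost
of any *compatible* bipartition of the previous column — one agreeing on
every read active in both columns. The smallest entry of the last column is
the optimum; stored per-boundary argmin pointers reproduce an optimal
bipartition, the corrections, and the haplotypes.

Key assumptions, stated plainly:

* **Sites are biallelic and given.** Variant calling, genotype likelihoods
  and BAM/VCF ingestion are upstream of this package; the fragment matrix
  is the interface.
* **Weights are taken as given.** How sequencing and mapping confidences
  are combined into one flip cost is an upstream policy; the simulator
  offers a phred transform, but the solver never reinterprets weights.
* **Default mode does not force heterozygosity.** Each part independently
  chooses its cheaper allele, so a noisy column may be called homozygous.
  `all_het = TRUE` constrains the two parts to complementary alleles — the
  convention used when all input sites are trusted heterozygous calls. The
  constrained optimum can never undercut the default one.

## Activity, gaps and blocks

A read is *span-active* at every column between its first and last call,
including internal call-free gaps (paired-end fragments). Gap columns
contribute zero cost but keep the read inside the per-column bipartition
state, which is what carries its part assignment across the gap: the
recurrence only transfers information through reads active in two
consecutive columns, so literal (call-only) activity would let the two ends
of a pair be phased inconsistently. The price is a coverage count that
includes gap-spanning reads. This convention is why gapped reads are
supported at all — a restriction to gapless matrices would rule out
paired-end data.

Columns covered by no read split the matrix into *blocks*, as do adjacent
covered columns with no spanning read. Blocks share no reads, so they are
phased independently and their optimal costs add; each emitted VCF record's
PS tag anchors to its block's first position.

`prune_to_max_coverage()` bounds the table sizes on deep data: scanning
left to right, over-covered columns drop their lowest-total-weight reads
first (ties: fewer calls, then higher index). The rule is a greedy
heuristic of this package — read selection is named as a feature in the
phasing literature but rarely specified — and it is deterministic, so no
RNG is involved.

## Gray-code enumeration and the parallel contract

Bipartitions are enumerated in binary-reflected Gray order
(`gray_rank_to_mask(r) = r XOR r>>1`): consecutive masks differ in one bit,
i.e. one read changes part, so the four per-part flip costs update in O(1)
per step (a read has at most one call per column). Ranks, not masks, are
what gets chunked for parallel evaluation; a chunk starting at rank r
enters the sequence at *Gray* mask g(r) — the second of two 4-rank chunks
of a 3-bit space starts at 110, not 100 — and initialises its part costs
from scratch once.

One column's evaluation is algebraically a map-reduce: disjoint rank chunks
are scored independently (each a pure function of the matrix, the inherited
projection and its range), and each chunk's per-key minima — keyed by the
assignment of reads shared with the next column — are merged by a reduce.
Scheduling is irrelevant to the result because the reduce takes a minimum
with a *value* tie-break: among equal costs the smallest mask wins,
everywhere (reduce, backtracking start, projection argmins). The original
parallel formulation tolerated run-to-run variation among cost-equal
optima; this package promotes determinism to a guarantee, because
reproducibility is worth more than the freedom, and tests byte-identity
across worker counts. `workers` forks map tasks with `parallel::mclapply`;
`chunksize` (default 4096 ranks) sets task granularity; columns below
`parallel_threshold` (default coverage 20, where a column's work starts to
dominate scheduling overhead) are evaluated as a single range and spawn no
tasks.

Two representation notes. Cost tables are indexed by plain mask value, with
Gray order only as iteration order, keeping projection lookups O(1).
Chunk-local minimum tables are sparse — only the keys a chunk actually
touches, at most two per rank — while the reduced projection table is dense
over the 2^|shared| key space; a dense per-chunk table would allocate that
space once per chunk for no benefit.

### Symmetry halving

Swapping the two parts of every bipartition leaves all costs unchanged, so
`halve_symmetry = TRUE` pins the first active read of each column to part 0
and enumerates 2^(c−1) masks, recording each mask and its complement. The
emitted tables and results are identical to full enumeration (the tests
assert this), and the work counter halves, matching the O(m·2^(cov−1))
complexity usually quoted for this algorithm. Full enumeration stays the
default for symmetry with the per-mask reference implementation.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `all_het` | `FALSE` | force complementary part alleles per column |
| `halve_symmetry` | `FALSE` | enumerate 2^(c−1) masks per column |
| `hard_coverage_limit` | 25 | refuse columns needing > 2^25-entry tables (~a desktop's memory); prune instead of thrash |
| `workers` | 1 | forked map workers; never affects results |
| `chunksize` | 4096 ranks | map-task granularity |
| `parallel_threshold` | 20 | minimum coverage to chunk a column |

## Numerical and degenerate-input choices

* Weights are decimal numbers; all fixtures use small integers so that ties
  are exact and Gray-incremental versus per-mask agreement can be asserted
  with `identical()`, not a tolerance. Float weights work, with the usual
  summation caveats; within one run, chunk boundaries depend only on
  `chunksize`, so summation order — hence every bit of the result — is
  reproducible for any worker count.
* Tie-breaks, exhaustively: smallest mask among equal-cost bipartitions;
  allele 0 when a part's two targets cost the same (default mode); the
  (R→0, S→1) orientation on an all-het tie; pruning drops fewer-call then
  higher-index reads among equal weights.
* A part with no call at a column emits `-` there in default mode, the
  complement of the other part under `all_het`; a column whose active reads
  are all gapped emits `-` on both.
* An empty matrix (m = 0 or no fragments) phases to cost 0 with no blocks.
  A projection over an empty shared set collapses to one key holding the
  global column minimum; the same rule anchors the first column (inherited
  cost 0) and the final optimum.
* The first column of every chunk is initialised from scratch; there is no
  numeric drift path from chunking because every mask's cost is local cost
  plus one table lookup.

## The simulator: what it emulates and what it does not

`simulate_dataset()` generates the conditions the solver is meant for:
all-heterozygous truth (haplotype 2 the complement of haplotype 1), reads
with uniform starts and geometric-ish lengths *measured in SNP columns*
(the DP never sees bases), a fair-coin source haplotype per read,
independent per-call flips at `error_rate`, and phred or fixed weights.
Paired mode concatenates two call runs around a call-free gap, exercising
the span-active machinery. Defaults — coverage 15, error rate 1 % (5 % as
the pessimistic variant), read length 10 columns, about a 10 kb read at
human SNP density — mirror the long-read benchmark regime this algorithm
targets (substitution rates of 1–5 %, datasets pruned to maximum coverages
of 15–25). The phred weight is capped at 60 when `error_rate = 0`, where
the transform is undefined.

Not emulated: base-level sequence and indels (an indel rate shapes
alignments, not the SNP-space matrix), mapping artifacts, genotyping error,
non-heterozygous sites, and correlated errors. Passing the simulation suite
therefore shows the solver and metrics are correct under the stated noise
model; it does not certify accuracy on real data, where weights are not
i.i.d. and errors cluster.

Everything is driven by one seed: haplotypes first, then per read start,
length(s), gap, source, error flags, in that order.

## Evaluation metrics

`phasing_accuracy()` reports, pooled over blocks: the **switch error
rate** (adjacent phased heterozygous site pairs whose relative phase
disagrees with truth), the **site error rate** (phased sites mismatching
truth under the better per-block orientation), and the **phased fraction**
(phased columns over block columns). The informal "error rate" of the
phasing literature is sometimes the one, sometimes the other, so both are
reported explicitly; both are invariant under swapping the predicted pair.
`wmec_of_assignment()` and `brute_force_optimum()` form the independent
scoring path used throughout the tests: the DP's optimum is checked against
exhaustive enumeration on small instances rather than against itself.

## Problem sizes used in the test suite

Chosen so the whole suite runs comfortably on one CPU: oracle equivalence
on 200 random matrices with at most 8 reads and 6 columns (where 2^n
enumeration is exact and instant); incremental-versus-naive agreement up to
coverage 12; determinism over 50 matrices × workers {1, 2, 4};
perfect-recovery at m = 200, coverage 10, 20 seeds; and the
coverage-versus-accuracy trend at physical coverages 5/10/15 with a
max-coverage-16 prune (m = 150, nine seeds, 5 % errors) — a scaled-down
analogue of the published 15×/20×/25× series, testing the direction of the
trend, not its published magnitudes.

## Known limitations

* Cost tables for a block are held in memory; coverage is hard-capped (2^25
  entries per table) rather than spilled to disk or compressed. Very deep
  data must be pruned first.
* The pruning heuristic is greedy, not an optimal read selection.
* Default-mode haplotype output leaves `-` where a part is silent; no
  imputation is attempted.
* Accuracy on real long-read data depends on the upstream weight model,
  which this package deliberately does not define.
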