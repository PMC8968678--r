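---
title: "Designing Tm-uniform oligo sets for gene synthesis with OligoTiler"
author: "OligoTiler authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing Tm-uniform oligo sets for gene synthesis with OligoTiler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OligoTiler)
```

## The design problem

Gene synthesis by ligase chain reaction (LCR) or assembly PCR stitches a
long double-stranded gene together from short synthetic
oligodeoxynucleotides that anneal over shared *overlap regions*. When the
overlaps melt at different temperatures, some junctions are unstable at the
annealing temperature of the reaction while others misprime, and assembly
error rises. The design goal is therefore a set of oligos whose overlap
duplexes have melting temperatures (Tm) as uniform as possible.

For gapless assembly the observation that makes the problem tractable is
that consecutive oligos abut exactly, so the gene *is* the serial
concatenation of the overlap regions: designing Tm-uniform overlaps is the
same as partitioning the sense strand into consecutive segments of
near-equal Tm. OligoTiler represents such a partition as a `Segmentation`
(0-based, half-open breakpoints) and optimises a single objective
throughout: the sample standard deviation (`tmDeviation`, divisor $n-1$) of
the per-segment Tm profile.

Oligo $j$ then spans segments $j$ and $j+1$; odd-numbered oligos sit on the
sense strand and even-numbered ones on the antisense strand, so each
interior segment is exactly the duplex shared by two consecutive oligos.
This shingled layout closes properly only when the segment count is odd,
which is why a short removable tail is appended to the 3' end when needed.

## Melting-temperature model

Tm is computed from the unified nearest-neighbor parameter set (stacked
dinucleotide $\Delta H^\circ,\Delta S^\circ$ terms plus terminal A·T / G·C
initiation terms; the table ships as
`inst/extdata/nn_santalucia1998_unified.tsv` so an alternate set can be
swapped in). For a duplex of length $\ell$ under conditions
$(C_T, [\mathrm{Na}^+], x)$:

$$
T_m \;=\; \frac{1000\,\Delta H}
 {\Delta S + 0.368\,\tfrac{N_{\mathrm{phos}}}{2}\ln[\mathrm{Na}^+]
  + R\ln(C_T/x)} \;-\; 273.15,
\qquad N_{\mathrm{phos}} = 2(\ell-1),
$$

with $R = 1.987\ \mathrm{cal\,mol^{-1}K^{-1}}$. This is the
phosphate-counted entropic salt correction; the symmetry factor $x$ is 4
for ordinary duplexes and 1 for self-complementary ones (which also receive
the tabulated symmetry entropy term). Defaults — $C_T = 2\times10^{-7}$ M,
$[\mathrm{Na}^+] = 0.05$ M, $x = 4$ — are typical assembly-PCR conditions.
Mismatch and dangling-end thermodynamics, divalent-cation corrections and
secondary-structure screening are out of scope; dedicated tools exist for
hairpin/repeat screening and can be applied to the emitted oligos.

Internally a cumulative-sum engine makes the Tm of any segment of a fixed
gene an $O(1)$ lookup, which is what keeps the refinement sweeps and the
candidate grid cheap. Because cumulative sums accumulate rounding noise of
order $10^{-8}$ °C, all *selection scores* (greedy cuts, tail growth) are
rounded to $10^{-6}$ °C before comparison so that exact ties — e.g. on
homopolymers — resolve by the documented tie-break rules rather than by
floating-point summation order.

## Stage 1: greedy segmentation

Segment lengths are confined to a band, by default 20–30 bp, which makes
oligos of roughly 40–60 bp. The first *two* segments are chosen jointly:
all $(n\times n)$ length pairs in the band are enumerated and the pair with
the least $|T_m^{(1)} - T_m^{(2)}|$ wins (ties: smaller total length, then
smaller first length). Every subsequent cut takes the band length whose
segment Tm is closest to the running mean of the segments already fixed,
ties to the shorter cut. Cuts are restricted to lengths that leave a
remainder of at least the minimum segment length; when no such length
exists the full band is used and the resulting undersized remainder is
passed to tail handling. A remainder that already fits the band is consumed
as the final segment. The original description of this stage pins down only
the first-two-segments rule; comparing later cuts against the *running
mean* (rather than, say, the previous segment only) is this package's
choice — it is the natural extension of "least deviation" and it is exactly
the quantity the next stage then polishes.

## Tail handling

`ensureOddSegments` restores two invariants after the greedy stage: no
remainder, and an odd segment count. A pure parity tail appends one new
segment; an undersized remainder is absorbed into a new full segment; when
both apply in a way that would leave the count even, two segments are
appended. Tail bases are chosen greedily one at a time from {A, C, G, T},
each minimising the distance between the growing segment's Tm and the
running mean, and the final length in the band with the closest Tm wins
(shortest on ties). For the very first base of an all-tail segment the
"Tm" of a 1-mer is defined from its doubled initiation terms — a
deterministic seed for the greedy rule rather than a physical quantity. Any
fixed rule would serve; this one keeps the objective uniform and is easy to
replay independently, which the test suite does. The tail always sits at
the 3' end of the sense strand, so a single downstream PCR with primers
matching the original termini removes it.

## Stage 2: iterative boundary refinement

Each iteration enumerates all single-boundary moves of ±1..3 bp (the
radius is configurable) that respect the length band of both flanking
segments, and accepts the single best move — but only if it lowers the
exact profile SD by at least the convergence threshold, 0.001 °C by
default. The SD is bounded below by zero and every accepted move improves
it by at least the threshold, so termination is guaranteed; in practice
convergence is rapid at this threshold. The move's improvement is
re-verified against a from-scratch SD computation before acceptance so the
per-move guarantee is exact rather than an artifact of incremental
arithmetic. Accepting only the per-sweep best (rather than all improving
moves) is this package's concrete realisation of the iteration stage; it
makes the accepted-SD trace strictly decreasing, which is the contract the
tests assert. Refinement is a local search: it is idempotent at its fixed
point but cannot guarantee a global optimum.

## Stage 3: dynamic programming over shrunk candidates

For gapped PCR assembly the search space widens: each segment may be shrunk
by 0..`shrinkMax` (default 2) bases at each internal end, producing a
*candidate column* of up to $(\mathrm{shrinkMax}+1)^2$ variants per
position (outer ends of the terminal segments are never shrunk — the gene
termini must stay covered). Choosing shorter candidates deletes bases from
the overlap regions; each junction gap is bounded by $2\cdot$`shrinkMax`
bases, and the deleted bases remain covered by exactly one strand, so
polymerase extension restores them during assembly.

The objective — the SD of the chosen Tm profile — is not additive over
columns, so it cannot drive a dynamic program directly. The standard
decomposition fixes a reference temperature $\mu$ and minimises
$\sum_i (T_i - \mu)^2$, which *is* additive. Two facts make a $\mu$-scan
exact rather than approximate:

1. the SD-optimal selection $S^\*$ minimises the decomposed cost at
   $\mu^\* = \operatorname{mean}(S^\*)$ (otherwise a cheaper selection at
   $\mu^\*$ would have a smaller SD, a contradiction);
2. the optimal selection as a function of $\mu$ is piecewise constant,
   changing only at midpoints of within-column candidate-Tm pairs.

`muGrid` therefore contains, besides the user-controlled fixed-step scan
(0.01 °C by default) and the unshrunk selection's mean, one interior point
of every interval between consecutive within-column midpoints. With that
grid the scan provably recovers the global optimum, and the test suite
checks equality against exhaustive enumeration to $10^{-9}$ on small
instances. A consequence worth noting: refining the step size can never
worsen the result, and with the midpoint points present it cannot improve
it either.

For each $\mu$ the minimisation runs as a Viterbi pass whose state at
column $i$ is the *pair* of choices at columns $(i-1, i)$; each transition
minimises over the choice at column $i-2$, i.e. the recurrence ranges over
$N^3$ transition triples per column — the three-column window with
$O(LN^3)$ total work. Because the per-candidate cost is additive, the
implementation evaluates the predecessor minimum once per $(i-1)$-choice
and vectorises over the $\mu$ grid; the `transitions` slot of the result
records the number of triples the recurrence ranged over, which is the
quantity the complexity test checks. Ties across $\mu$ are broken toward
fewer deleted bases, then grid order; backtracking ties go to the lowest
candidate index (candidates are ordered by total shrink, then left shrink,
so a lower index means fewer deletions).

Because the unshrunk selection is always in the search space, the DP
objective can never exceed the SD of the segmentation it started from;
combined with refinement only ever improving on the greedy result this
yields the dominance chain
$\mathrm{SD}(\mathrm{dp}) \le \mathrm{SD}(\mathrm{refined}) \le
\mathrm{SD}(\mathrm{greedy})$, which the acceptance suite asserts on
seeded fixtures of 0.5–3 kb. The chain holds as stated when the DP runs on
the refined segmentation; the default gapped pipeline instead feeds the
greedy result straight to the DP (`refineInGapped = FALSE`), trading that
guarantee against the middle stage for less work — the DP still dominates
whatever segmentation it is given.

## Worked example

```{r pipeline}
gene <- generateFixture(900, gcFraction = 0.5, seed = 11)
res <- runPipeline(gene, AssemblyConfig(mode = "gapped", refineInGapped = TRUE),
                   verbose = FALSE)
res$sdTrace
res$oligoSet
head(oligoLayout(res$oligoSet), 4)
```

The per-stage SDs decrease monotonically; `assemblyStats()` reports the
overlap-region and whole-oligo Tm means and SDs (sample and population),
and the suggested annealing temperature for the assembly reaction is the
mean Tm of the final oligo set.

## What the synthetic fixtures do and do not show

`generateFixture` draws i.i.d. bases at a requested GC fraction and can
splice in adversarial AT- or GC-rich islands. This reproduces the features
the optimisation actually responds to — local composition heterogeneity and
its effect on segment Tm — and the seeded generator makes every pipeline
run byte-reproducible. It does *not* emulate codon structure, repeats or
secondary-structure-prone motifs of natural genes; passing tests therefore
demonstrate the optimisation contracts (dominance, optimality, geometry,
determinism), not wet-lab assembly performance on a specific gene. On
random sequences the absolute SDs tend to be larger than on codon-optimised
genes, but every reported number is computed, not assumed.

Problem sizes used by the checked examples were chosen to exercise each
regime: 50 instances small enough for exhaustive enumeration
($L \le 6$ columns, $N \le 9$ candidates) for DP optimality, 100 fixtures
of 0.5–3 kb for the dominance chain, and a 3 kb end-to-end run for the
full invariant set.

## Numerical and degenerate-input choices

* Sample SD (divisor $n-1$) is the optimisation objective and the reported
  statistic; the population SD is additionally printed in reports for
  comparability with tools that use it.
* Reported temperatures are printed to 4 decimal places.
* Inputs shorter than twice the minimum segment length are rejected (no
  two-segment design exists); ambiguous bases are rejected with the
  offending position named.
* `shrinkMax = 0` degenerates the DP to a single selection and makes the
  gapped design byte-identical to the gapless one on the same
  segmentation.
* A candidate floor (default `minSegmentLen - 2*shrinkMax`) drops
  over-shrunk candidates; an empty column is an error rather than a silent
  repair.

## Known limitations

* Refinement is a steepest-descent local search; only the DP stage carries
  an optimality guarantee, and that guarantee is relative to its
  shrink-bounded search space around the segmentation it is given.
* Overlap-Tm statistics summarise the interior segments (the duplexes two
  consecutive oligos actually share); terminal segments are covered once
  and contribute to oligo Tm statistics only.
* No screening for hairpins, repeats or off-target priming; high-GC or
  repeat-dense genes should be pre-screened with a dedicated tool.
* Tail composition is a deterministic design choice, not an optimised
  quantity; any band-length tail keeps the parity invariant.
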