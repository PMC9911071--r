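---
title: "Methods: detecting and characterizing a shattered chromosome"
author: "shatterscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and characterizing a shattered chromosome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, parameter choices, and numerical decisions
behind shatterscan, in the order the pipeline runs them. The package targets
a specific biological situation: a single individual — here modelled on a
trisomic *Arabidopsis* offspring of a parent-A/parent-B hybrid mother and a
parent-A father — in which one chromosome arm shattered into fragments that
reassembled in random order and orientation, and the derivative chromosome
was co-transmitted with an intact homolog through a meiotic
nondisjunction. Three orthogonal genomic signals identify and characterize
such an event: binned read dosage, discordant read pairs at novel DNA
junctions, and parental allele dosage at diagnostic SNPs.

## Dosage

Reads are assigned to non-overlapping bins by their leftmost mapped
coordinate (midpoint assignment would change nothing material and is harder
to reason about at bin edges; half-open bin arithmetic makes a read at
position 5,000 fall in the second 5-kb bin). Two bin sizes are routinely
useful: 100 kb for genome-wide overview, 5 kb to resolve individual
fragments within a shattered region.

The sample is normalized against pooled controls:
`rel = 2 * (s_b/S) / (c_b/C)`. Two numerical guards matter.

* **Control floor.** Bins with a pooled control count below 10 reads are
  masked rather than divided (a near-zero denominator turns sampling noise
  into arbitrarily large ratios). The value 10 bounds the multiplicative
  noise contribution of the control at roughly 1/sqrt(10) = 32% per masked
  threshold bin, and in practice masks only assembly gaps and collapsed
  repeats.
* **Median recentering.** Totals-based scaling assumes aneuploidy is a
  negligible fraction of the genome. At the scales this package simulates
  (and in heavily rearranged samples generally) that assumption fails: a
  trisomic arm inflates the sample total and displaces every diploid bin
  below 2. The ratios are therefore recentered so the genome-wide median
  unmasked bin equals exactly 2, in two passes — a plain median first, then
  the median of bins that look neutral (1.5–2.5) after the first pass,
  which removes the residual bias that appears once aneuploid bins are a
  sizable minority. This is the robust "most of the genome is diploid"
  assumption every read-depth dosage tool makes; it fails only if more than
  half the unmasked genome deviates from diploid, which the package treats
  as out of scope. `center = "none"` restores the plain ratio.

CNV states use thresholds 1.5 and 2.5, midway between the integer dosage
anchors 1 (heterozygous loss), 2 (diploid) and 3 (single-copy gain); both
are explicit arguments, since no principled value exists between the
anchors. The shattered-region detector slides a window of 500 kb (default;
100 kb in the desk-scale demo) and reports maximal runs of bins where some
covering window holds at least 20% CNV bins — deliberately permissive,
because a shattered region mixes gain bins (retained fragments) with
neutral bins (lost fragments).

## Junction discovery

A novel junction is an adjacency between two reference loci that are
distant in the reference but contiguous in the sample. Its read-pair
signature is a cluster of pairs whose mates map more than 2,000 bp apart or
to different chromosomes. Parameters, with rationale:

* `min_distance = 2000` bp — the discovery threshold; junctions whose two
  breakpoints are closer than this in the reference are invisible to
  pair-distance evidence by construction (the simulator's truth tables make
  this blind spot explicit, and tests measure recall against *detectable*
  junctions).
* `radius = 500` bp — clustering and control-matching radius, about one
  insert size plus one read length, the positional spread of pairs
  spanning a single junction.
* Control subtraction implements the two-control contract: a cluster is
  dropped if any control shows a matching cluster (both sides within the
  radius, strands agreeing). The operation is idempotent.
* Support threshold `max(3, ceil(mu + 3*sqrt(mu)))`, with `mu` the mean
  support of control distant-pair clusters scaled by the depth ratio. This
  is a Poisson-tail argument (three standard deviations above the expected
  artifact support), declared as this package's rule; with clean controls
  it reduces to the floor of 3 supporting pairs.

### Assembly and anchoring

Each surviving cluster is resolved by local assembly. The read pool is all
reads mapped within 400 bp of either side plus all mates of the cluster's
member pairs. Seeds are reads that disagree with the reference
(junction-spanning reads), member reads first; up to eight seeds are tried,
and a resolved call must anchor within the cluster's own loci (radius +
window), which prevents a cluster from resolving into a *neighboring*
junction when two junctions share a fragment boundary.

Extension is greedy with exact 31-mer suffix seeds and **per-column
majority consensus**, with two refinements that simulated data showed to be
necessary:

* Columns where the cluster's own member reads vote are decided by the
  member majority; two comparable member factions (within 10% support) are
  a true branch — reads from two distinct junctions are mixed — and the
  assembly is reported `branched`, never guessed.
* Columns with no member evidence need at least two covering reads, and
  near-ties (second allele at 90% or more of the first) truncate the
  extension. Without the two-read rule, a lone read from the intact
  homolog can lock a heterozygous variant allele into the contig; a single
  such base later stops the maximal-exact-match anchor dead and turns a
  microhomology junction into a spurious "insertion".

Breakpoints come from maximal exact-match anchoring of the two contig
flanks (20-mer seed, then extension, on either strand), requiring at least
30 matched bases per flank; a flank whose best match length is achieved at
more than one reference locus fails the no-multiple-mapping contract and
the call is excluded. Anchor ties break toward the longer match, then the
leftmost coordinate. The anchor geometry then *is* the repair
classification — with left flank ending at contig position `a` and right
flank starting at `b`:

* `b <= a`: microhomology of length `a - b + 1` (an identical sequence on
  both sides, present once at the junction). Lengths above 29 bp are
  reported but flagged out of range, since the 1–29 bp range is an
  observation about real junctions, not a rule.
* `b == a + 1`: perfect join.
* `b > a + 1`: insertion; the gap sequence matches neither flank by
  construction of maximal anchors, so an insert containing coincidental
  homology still classifies as insertion.

This classification is stable under reverse complement (flanks swap roles;
the overlap length is invariant), which the tests assert.

## Reconstruction

Junction calls over the CNV cluster imply a segmentation: a `tail` side at
position p cuts after p, a `head` side at p cuts after p-1, so the two
sides of one fragment boundary imply the same cut and the segments are
exactly the inter-breakpoint fragments. Each junction attaches two specific
segment ends; ends claimed by more than one call keep the
highest-support call (the spec of real data — which call wins at a
contested end — is not observable, so support is the declared tie-break).
Maximal simple paths are the reconstructed fragment runs; cycles (possible
with imperfect calls) are broken at their lowest-support edge. Chains are
normalized so the leftmost segment reads '+', making reconstructions
comparable up to whole-chain reversal, which is the natural equivalence (a
derivative chromosome has no intrinsic left end).

One property deserves its caveat: deleting one call from a k-junction
chain splits it into exactly two chains totaling k-1 junctions *provided*
the deleted junction's cuts survive through the complementary sides of its
boundaries. Deleting a junction at a boundary shared with a chain terminus
merges two segments across the old cut and can close the remainder into a
cycle, which is then broken at the weakest edge (k-2 junctions). The test
suite asserts the clean-split property on junctions satisfying its premise.

Junctions with a breakpoint outside the target region are dropped with a
message rather than extended with out-of-region segments: the pipeline
reconstructs within the CNV cluster, where essentially all calls of a
genuine chromothripsis event fall.

## Haplotype dosage and meiotic staging

At parent-diagnostic SNPs (each parent near-fixed, minor fraction at most
0.1 at depth at least 10, for different alleles), the parent-B read
fraction is pooled **read-weighted** within 10-kb bins — not averaged per
SNP — because depth varies with the CNV landscape and per-SNP averaging
would overweight thin sites. Bins with fewer than 20 informative reads are
masked (at 30x and typical SNP densities this keeps binomial noise per bin
near or below the classification tolerance).

Expected frequencies are exact copy fractions: 1/2 for {A,B}, 1/3 for
{A,A,B}, 0 and 2/3 for the meiosis-II cases {A,A,A} and {A,B,B}. Bins
classify to the nearest of {0, 1/3, 1/2, 2/3} within a tolerance of 0.06,
chosen below half the minimal state gap (1/12 = 0.083) so assignments are
unambiguous; anything farther is "other".

The staging rule on the trisomic region (which the dosage stage supplies):
meiosis I requires both the 1/2 and 1/3 states — two *different* maternal
haplotypes co-inherited, with 1/2 marking lost fragments; dominance of 2/3
or 0 states means two *identical* maternal haplotypes (meiosis II); uniform
1/2 is balanced. A state must cover at least 5% of classified bins to count
as present. The pericentromeric subregion, when it holds at least five
classified bins, overrides the whole region: crossovers rarely alter
pericentromeric haplotypes, so it is the most reliable witness of
mis-segregation timing. Two caveats are inherent to the allele signal and
documented rather than hidden: a region that is all 1/3 with no lost
fragments still reads meiosis I (the 1/3 state itself requires two
different maternal haplotypes); and a balanced all-A offspring is
indistinguishable from a meiosis-II {A,A,A} trisomy by alleles alone — the
0-state verdict presumes the region was independently shown to be
trisomic.

## Enrichment

The statistic is the fraction of breakpoints whose centered window (1 kb
and 10 kb, clipped at chromosome ends) touches at least one track
interval — binary per breakpoint, robust to window clipping, rather than
base-pair overlap (available reasoning: a frequency of breakpoints "near"
a feature is what the binary statistic measures directly). The null is
uniform placement, genome-wide or within the shattered region; the
within-region null is the right comparison for breakpoints that all come
from one CNV cluster, where genome-wide density differences would dominate.
The p-value is empirical and two-sided with the +1 correction:
`p = (1 + #{|f_perm - mean| >= |f_obs - mean|}) / (n_perm + 1)`, so
p is never 0 and is calibrated under its own null (the test suite checks a
5% +/- 2% rejection rate over 500 null replicates). Benjamini–Hochberg
adjusted values are emitted in a clearly separate column as an extension;
the primary columns are raw, as feature-enrichment tables conventionally
report.

## The synthetic-data generator

The generator emulates, with full ground truth: a uniform-composition
reference genome (GC 0.36, the *Arabidopsis*-like default); two parental
haplotypes (parent A is the reference; parent B carries substitutions at a
per-bp rate, default 0.002); a shatter event (uniform fragment cuts with a
200-bp minimum, uniform loss at rate 0.1 — fragment loss to micronuclei is
real but unquantified, so a modest default — uniform random order and
orientation, repair classes drawn from the 63.8/11.2/25 mix); offspring
karyotypes for balanced transmission and meiosis-I/II nondisjunction, the
paternal copy always parent A, with an optional maternal crossover; and
paired reads (100 bp, insert 300 +/- 50 truncated at the read length,
30x — stand-in values, since the original libraries' geometry is not
specified) with idealized alignments.

Design notes:

* **Microhomology is planted.** Random sequence contains no long shared
  flanks, so for a microhomology junction the m bases entering the
  junction from the right are set equal (in the reference, inside the
  shattered region) to the m bases entering from the left, and the
  derivative keeps one copy. The bases immediately beyond every junction
  are additionally adjusted so maximal exact anchoring stops exactly at
  the planned breakpoints — otherwise coincidental 1–2 bp matches would
  blur the truth labels (a "perfect" join in random sequence shows a fake
  1-bp microhomology about half the time). `shatter()` therefore returns
  the lightly edited genome, and all edits stay within the region.
* **Idealized alignments.** Each mate is reported at the reference locus
  of the piece holding the majority of its bases, with the start
  back-extended so every record is full-length M — no soft clips, no
  mapping error, no base error unless `error_rate > 0`. A pair spanning a
  junction is thus reported at the junction's two loci, which is the
  idealization of what a real aligner does to such pairs. Bases of a
  spanning read past the junction misreport against the reference at its
  anchor — as real soft-clipped bases would — and are exactly what the
  assembler's seed selection looks for.
* **Coverage model.** Insert positions are uniform over the karyotype's
  physical sequence, so expected per-base coverage is `depth * c / 2` for
  copy number c, and read dosage is linear in copy number by
  construction; the tests verify the realized slope.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: sequencing and mapping error, GC and
mappability bias, repetitive sequence (the genome is i.i.d. random, so
flank anchoring is nearly always unique; real pericentromeric repeats
defeat unique anchoring, which is precisely why real junction sets are
incomplete), PCR duplicates, and chromatin-informed breakpoint placement
(simulated breakpoints are uniform, so enrichment tests on simulated data
check calibration, not biology).

## Conventions and problem sizes

All internal coordinates are 1-based inclusive — the natural convention for
R strings and for SAM/GFF-style reporting; BED input/output converts at the
boundary. All randomness flows through named integer seeds; identical
seeds give identical outputs, and the pipeline derives per-stage seeds from
one master seed.

The test suite and the acceptance script run on deliberately desk-scale
problems — genomes of 0.2–2 Mb, shattered regions of 0.15–0.6 Mb with 8–21
fragments, 30x depth, 500–2,000 permutations, 20 replicates per meiotic
stage — sizes chosen so the full suite completes in a few minutes on one
CPU while every rate being tested (recall, precision, calibration) still
has enough events behind it to be meaningful.
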