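---
title: "Simulating and scoring pooled-BAC versus WGS assemblies"
author: "poolscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and scoring pooled-BAC versus WGS assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(poolscore)
```

## The problem

Two strategies dominate the sequencing of large plant genomes: whole-genome
shotgun (WGS), where reads are drawn from the entire genome at once, and
clone-based approaches, where bacterial artificial chromosomes (BACs) forming
a minimum tiling path (MTP) over the genome are sequenced in pools of a few
megabases each. Pooling localises assembly errors to individual pools and
prevents distal chimeric joins, at the cost of library construction and a
physical map. `poolscore` provides the in-silico machinery to compare such
regimes: simulators for pyrosequencing-style (454) reads and Sanger BAC-end
sequences (BES) over MTP pools, a BES-driven pseudomolecule constructor, and
five assembler-independent correctness scores computed against the known
reference.

The package deliberately stops short of running an assembler or BLAST:
assemblies are produced elsewhere (or by the built-in corruption fixture
generator), and alignments enter either as BLAST tabular files or from the
built-in exact anchor matcher at test scale.

## Reference material

`make_synthetic_reference()` generates references with controlled GC
fraction, a controlled fraction of bases inside homopolymer runs of length
three or more, and optional verbatim repeat families. The generator emulates
the compositional spread of the plant genomes this methodology targets (GC
roughly 0.33-0.47 and widely varying repeat content); it does not emulate
gene structure, isochores, or the interspersed repeat taxonomy of real
genomes, so passing tests demonstrate parameter recovery and scoring
correctness, not assembler performance on real DNA. Homopolymer runs are
placed as disjoint spaced blocks (lengths 3-8) over a run-free background,
and a rebalancing pass removes the slight GC bias that run placement
introduces; both composition targets are met within 0.02 from about 100 kbp.

Real references with ambiguity codes are prepared with
`replace_ambiguous()`: every N is replaced by a base drawn with probability
proportional to that base's frequency in the non-N portion of the same
sequence, estimated per input sequence (simple, testable, and faithful to
per-genome frequency replacement).

`build_mtp()` draws clone sizes from a normal with mean 145 kbp restricted
to 47-191 kbp and overlaps with mean 36 kbp restricted to 0.6-113 kbp —
the published summary statistics of a real rice tiling path; the full layout
is not public, so a distributional reconstruction is the natural choice. One
template layout covering 3 Mbp is drawn and then repeated (shifted) to cover
larger spans, so larger pools reuse the same MTP structure rather than
drawing an independent one. `partition_pools()` accumulates clones greedily until the pool
span first reaches the target (clones are atomic and never split — the
sensible reading of pooling physical clones); a trailing remainder smaller
than half the target merges into the previous pool. At genome scale
(119 Mbp, 3 Mbp target) this yields 39-40 pools depending on the draw.

## The 454 read simulator

Coverage is deliberately non-uniform. Each sequence is divided into 100 bp
windows; each window receives a raw density max(N(5, 1), 0), and densities
are normalised to sum to one (`make_coverage_model()`). A read is assigned
to a window with probability equal to the window density and starts
uniformly within it.

Read lengths are drawn from normals with the regime's moments — linear
reads 350 +/- 150 bp, paired-end reads 170 +/- 70 bp — rounded and clamped
below at 30 bp. Clamping (rather than resampling the lower tail) keeps the
realised means within one percent of the nominal values, which is the
recovery contract the tests check; with resampling, the paired mean would
drift to about 174 bp. Length and quality profiles resampled from real 454
runs are the gold standard but are instrument- and sample-specific, so the
parametric model is the default and `draw_read_length(profile = ...)`
accepts a drop-in empirical profile (one observed length per draw). Quality
strings are a constant Q30 placeholder for the same reason.

Error injection is homopolymer-aware. With `totalErrorRate` the sum of the
substitution (0.1%), insertion (0.5%) and deletion (0.5%) rates, each
nucleotide carries an error with probability `a * totalErrorRate` when its
maximal run has length at most two and `b * totalErrorRate` in runs of
length three or more, with a = 0.8 and b = 1.6. On a reference with a
quarter of its bases in long runs this yields an overall rate of
0.011 × (0.75·0.8 + 0.25·1.6) = 1.1%. The error probability is
per-nucleotide Bernoulli (matching the per-nucleotide phrasing of the
protocol), not per-run. Within a single run, the first insertion locks out
deletions for the rest of the run and vice versa. Two details the protocol
leaves open are fixed as follows: inserted bases duplicate the run
nucleotide (the dominant 454 over-call mode) and substitutions draw
uniformly from the other three bases. Error logs record original-read
coordinates, so observed rates are measured per extracted (pre-error) base.

Paired reads are generated by placing inserts via the same window model
(insert length 3 kbp +/- 20 bp by default; several libraries, e.g.
3 kbp + 8 kbp at equal shares, can be mixed), extracting one read from each
insert end facing inward with the downstream mate reverse-complemented, and
labelling both mates with the insert index. Coverage counts read bases only,
and generation stops at the first read crossing the requested fold coverage.
Strand is uniform for linear reads (the protocol is silent); origin
coordinates are always recorded on the forward reference strand.

```{r reads}
ref <- make_synthetic_reference(2e5, gc = 0.4, homopolymer_frac = 0.25)
sim <- simulate_linear_reads(ref, coverage = 5)
sim
100 * nrow(sim$errors) / sim$origin_bases  # percent, expect about 1.1
```

## The BES simulator

`simulate_bes()` extracts two Sanger-style BES per MTP clone (one per end,
inward-facing, right end reverse-complemented) plus additional singleton BES
placed as a homogeneous Poisson process with one expected occurrence per
20 kbp. Whether additional BES come as mated pairs is not specified
anywhere; singletons are the minimal choice and suffice for ordering.
Lengths are uniform in 600-700 bp. Errors are per-nucleotide Bernoulli with
substitutions at 0.006% and indels at 0.0002% each — at these rates a BES
carries less than one erroneous base on average, so exact matching of BES
into scaffolds remains realistic at test scale. Records are sorted along the
reference and numbered; that `order_index` is the anchor ordering for
pseudomolecule construction.

## Pseudomolecule construction

Scaffold-versus-BES hits (BLAST tabular in practice, `match_bes_exact()` at
test scale) are filtered at E <= 1e-75 and identity >= 98%. Each scaffold is
keyed by the smallest MTP ordinal among its hits — "first BES" is read as
smallest MTP ordinal, not leftmost scaffold coordinate — and scaffolds are
sorted by that key. Orientation compares the scaffold positions of the
first- and last-ordinal BES hits; a single-hit scaffold defaults to forward
since the rule needs two distinct anchors. Key ties break by the
second-smallest ordinal, then name, with a warning. Placed scaffolds are
joined with exactly 70 X characters between consecutive scaffolds; unplaced
scaffolds are listed in a sidecar, reflecting that both regimes need a
physical map to place everything.

## Scoring

All scores derive from two per-position tables built from match intervals of
at least 1 kbp (the length filter applies to reference-assembly scoring
hits only, not to BES hits). For a reference of length n and assembly of
length m, `T[i]` is the closest matching assembly coordinate for reference
position i (negative for minus-strand matches, 0 when unmatched) and `U[j]`
is the closest matching reference position for assembly position j. Within
an interval the mapping is linear interpolation between the endpoints —
alignment-internal gaps are not modelled, which is exact for the built-in
matcher and a good approximation for high-identity BLAST hits. Ties on
|i - j| break to the smaller |j|, then smaller j: deterministic and
order-independent. Spacer characters (X/N) count in m but can never match.

The five scores, each in [0, 1] with 1 best:

* **Match (M)** rewards long contiguous matches: with matching segments u
  and gap segments v partitioning [1..n],
  M = (α Σ(|u|/n)^η₁ + β(1 − Σ(|v|/n)^η₂)) / (α + β), with
  α = β = 1 and η₁ = η₂ = 2 by default. The complement form of the gap term
  is the default because the additive form rewards gaps (a no-match table
  would score 0.5 and concentrated gaps higher); the additive form remains
  available as `variant = "literal"`. Matching segments are maximal runs of
  nonzero T that are also mapping-contiguous (the signed step stays in
  {0, 1, 2} with no strand flip); without that break, two abutting hits
  assembled megabases apart would masquerade as one long match.
* **Relocation (RL)** samples T every n/x positions (x = 10,000 by
  default), skips zeros, and counts order disagreements among the x'
  retained points: every pair whose |T| magnitudes decrease while positions
  increase adds 2 to #d, and RL = 1 − #d/(x'² − x'). Magnitudes are
  compared because strandedness is already penalised by I; equal values do
  not disagree; fewer than two points is vacuously 1. With x' equal to the
  number of nonzero entries the sampled score equals the exhaustive
  all-pairs computation, which the tests verify against a brute-force
  oracle.
* **Inversion (I)** = 1 − (#negative T entries)/l, where l is the number
  of matched reference positions; vacuously 1 when l = 0.
* **Redundancy (RD)** = #u/m, where #u counts reference positions occurring
  exactly once among the nonzero entries of U. Duplications and unmatched
  junk both depress it.
* **Coverage (C)** = l/n.

`score_assembly()` computes all five plus their sum, the combined ranking
statistic. `corrupt_assembly()` generates misassembled fixtures (inversions,
deletions, duplications, relocations) together with their exact truth
segments, so score recovery can be asserted against construction truth
rather than a matcher's output.

```{r score}
cr <- corrupt_assembly(ref, list(list(op = "invert", start = 50001, end = 110000),
                                 list(op = "delete", start = 150001, end = 170000)))
score_assembly(ref, cr$assembly, cr$segments)
```

`dotplot_segments()` exports the match intervals as orientation-labelled
segments for dot-plot rendering by any plotting front end.

## Numerical and scale choices

Tests and examples run on references of 0.03-2 Mbp and error-rate recovery
uses about 10 Mbp of read bases and 50 Mbp of BES bases — the smallest
sizes at which the published rates are measurable against their own
sampling noise (3 standard errors), chosen so the whole suite runs on a
laptop core in minutes. The anchor matcher is quadratic-safe only at test
scale; genome-scale comparisons should come through BLAST tabular input.
All simulators consume R's global RNG, so a single `set.seed()` makes an
entire pipeline — reference, MTP, reads, BES — byte-reproducible, which the
suite checks down to FASTQ file checksums.

## Known limitations

* No flowgram-level 454 simulation; error placement is per-nucleotide, not
  per-flow, and quality values are placeholders.
* The MTP is a distributional reconstruction of the published rice tiling
  path statistics, not the actual clone layout; pool counts at genome scale
  are therefore approximate (39-40 for 119 Mbp at 3 Mbp pools).
* Match intervals are treated as gap-free linear mappings; highly gapped
  BLAST hits will blur T/U by a few bases.
* The package evaluates assemblies; it does not produce them. Reported
  score magnitudes on real assemblers additionally depend on the assembler
  and its parameters.
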