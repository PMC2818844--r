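---
title: "Methods: promoter chromatin-state analysis on tiling arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter chromatin-state analysis on tiling arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromtile)
```

## The analysis problem

ChIP-chip on promoter tiling arrays measures, for each probe, the log2
ratio of chromatin-immunoprecipitated DNA over input DNA. With probes
tiling a window around every annotated transcription start site
(−2,000 to +500 bp here), the analytical task is to decide, per promoter
and per histone mark (H3K4me3, the active mark; H3K27me3, the Polycomb
repressive mark), whether the promoter is enriched — and from the two
marks jointly, whether it is *bivalent* (carries both). Downstream
questions are then set-level: how similar are two lineages' enrichment
maps (sharing fractions, Venn overlaps, Fisher tests), is a mark
over-represented on the X chromosome, and how does chromatin state
relate to expression measured in single cells.

`chromtile` implements that full path — peak calling with a
randomization FDR, MaxTen promoter scoring, replicate-concordant
enrichment calls and four-way classification, TSS-anchored metagene
profiles, and the comparative statistics — together with a synthetic
data generator that emulates the array design, so the whole pipeline is
testable end to end against planted ground truth.

## Peak calling

Peak detection works per track (one mark × sample × replicate):

1. **Hypothetical maximum.** `H = mean + 6·SD` of all probe ratios on
   the track (sample SD). Detection cutoffs are percentages of `H`,
   swept from 90% down to 15% in steps of 5% (16 levels, most stringent
   first). The step size is a configurable default; only the 90–15%
   range is fixed by the procedure being reimplemented.
2. **Window rule.** A probe is *above* a cutoff when its ratio strictly
   exceeds it. For every above probe, the 500-bp window starting at its
   midpoint is examined; if the window holds ≥ 4 above probes of the
   same promoter, all of them become peak members, and member sets
   sharing a probe are merged. Anchoring windows at above-probe
   midpoints gives exactly the same merged peaks as sliding the window
   at 1-bp resolution (any qualifying window can be shifted to start at
   its leftmost member); the test suite verifies this against a literal
   1-bp brute-force enumeration. Windows never cross promoter or
   chromosome boundaries.
3. **Randomization FDR.** The multiset of ratios is permuted uniformly
   across all probe positions of the track (20 times by default) and
   detection re-run at every level. `FDR(level) = mean permuted peak
   count / observed peak count`, capped at 1. Each observed peak is
   reported once, at the most stringent level at which it is detected,
   with that level's FDR. Permuting the whole track rather than within
   promoters preserves the global ratio distribution, which is what the
   cutoffs are defined on.

Strictness of ">" at the cutoff is a deliberate tie-break: it is
unambiguous under permutation ties. The permutation unit, step size and
scheme are reconstructions of a vendor procedure whose exact details
are not published; all are exposed as parameters of
`peak_call_params()`.

## Enrichment calls and classification

A promoter is *enriched* for a mark when a peak at FDR ≤ 0.1 is present
in both replicates (N = 2) or in at least two of three (N = 3) — peak
evidence only. The four-way state is then: `bivalent` if both marks,
`K4`/`K27` if one, `none` otherwise.

**MaxTen** (the highest mean of 10 consecutive probe ratios in genome
order, averaged across replicates) is computed for every promoter as a
continuous diagnostic score — the classic two-dimensional scatter of
MaxTen(H3K4me3) vs MaxTen(H3K27me3) colored by state is available via
`autoplot()` on the classification table — but never gates the
classification. Promoters with fewer than 10 probes fall back to the
mean of all their probes and carry a `short_promoter` flag rather than
being dropped, keeping the promoter universe stable for the overlap
statistics. When replicates disagree in number, all provided replicates
are averaged.

## Metagene profiles

Probe positions are expressed relative to the TSS in transcription
orientation (upstream negative on both strands) and averaged in 50-bp
right-open bins over the tiled window; replicates are pooled with every
probe observation weighted equally, and each probe contributes wholly
to the bin containing its midpoint. Bin width and replicate weighting
are package defaults, not claims about the original analysis. The
*null-peak* background class contains promoters whose probes all fall
strictly below the least-stringent (15%) detection cutoff. Note that
conditioning on "all probes below a threshold" shifts the whole
null-peak profile slightly downward (a truncation effect); flatness of
that profile should therefore be judged about its own mean, which is
how the test suite asserts it.

## Comparative statistics

Pairwise overlaps are reported as 2×2 contingency tables over the
promoter universe with sharing fractions in both directions, plus a
two-sided Fisher exact p-value using the conventional probability-mass
rule (sum of hypergeometric probabilities ≤ that of the observed
table). The Fisher universe is all promoters on the array — the
measurement frame — unless overridden. X-linkage is summarised as the
frequency of a target set among X-chromosome promoters divided by its
frequency elsewhere. Expression integration scores a gene *present*
when detected in at least half of the profiled single cells (10 of 20
by default, boundary inclusive; the threshold generalises to
⌈n/2⌉ for other cell counts) and reports the percentage of present
genes per chromatin class.

## The synthetic generator

`simulation_config()` defaults define the reference conditions used
throughout the tests:

| parameter | default | meaning |
|---|---|---|
| `n_promoters` | 2000 | promoters on the array |
| `probes_per_promoter` / `probe_spacing` | 20 / 125 bp | tiling of −2000..+500 |
| `state_distribution` | 0.50/0.25/0.15/0.10 | none/K4/K27/bivalent |
| `cross_lineage_sharing` | 0.80/0.34/0.22 | K4 mark / K27 mark / bivalent state |
| `signal_amplitude` | 1.5 log2 | planted peak height |
| `k4_center`, `k4_width` | −1150, 400 bp | H3K4me3 Gaussian bump |
| `k27_center`, `k27_width` | −1000, 500 bp | H3K27me3 bump (broader, nearer TSS) |
| `tss_dip_depth` | 0.4 log2 | nucleosome-depleted dip at the TSS (K4 only) |
| `noise_sd` | 0.3 log2 | i.i.d. per-probe replicate noise |
| `p_expressed` | 0.10/0.76/0.19/0.51 | P(expressed) per state |

Signal is a Gaussian bump in TSS-relative coordinates per planted mark;
H3K4me3 additionally subtracts a 150-bp-SD dip centred at the TSS,
emulating the nucleosome-depleted region of active promoters. The
H3K4me3 centre/width place the bulk of enrichment over roughly
−1,800..−500 bp; H3K27me3 is broader and declines more gradually toward
the TSS. Replicates share the planted signal and differ only in
i.i.d. Gaussian noise — no spatial autocorrelation, no amplification or
dye bias — so passing tests demonstrate correctness of the *procedure*,
not robustness to every artefact of real two-color arrays.

**Probe layout.** Probe midpoints sit at −2000 + 125·i (20 probes,
50-mers). The 125-bp pitch was chosen for two geometric reasons: 20
probes tile the 2,500-bp window exactly, and a half-open 500-bp window
then holds exactly four probes, so the "≥ 4 probes in 500 bp" rule is
exercised at its design point (at pitches above 166 bp the rule could
never fire; published promoter tiling designs use pitches around
100 bp). The true array's probe density is not published; both
parameters are configurable.

**Cross-lineage sharing.** The first lineage's states are multinomial.
For a derived lineage, each first-lineage mark is retained with the
configured per-mark sharing probability, bivalent promoters retain
*both* marks with the bivalent sharing probability (feasible when
`bivalent ≤ min(K4, K27)` and `K4 + K27 − bivalent ≤ 1`), and fresh
enrichments are drawn only from promoters carrying no first-lineage
mark, at rates that match the derived lineage's per-mark marginals in
expectation. Restricting fresh enrichment to unmarked promoters makes
the downstream-measured sharing fraction converge exactly to the
configured probability — the property the recovery tests assert — at
the cost of two documented approximations: with sharing = 0 the planted
sets are disjoint rather than independent, and the derived lineage's
*state*-level distribution is matched only as closely as the mark-level
constraints allow (at the defaults, its bivalent fraction is ≈ 0.092
rather than 0.100; the per-mark marginals are exact in expectation).

**Expression.** Detection per cell is Bernoulli: 0.7 for expressed
genes, 0.02 for silent ones. With 20 cells the ≥ 10-cell present rule
then recovers an expressed gene with probability 0.983, so the
class-level percentages recovered downstream sit ≈ 1–2 points below
the configured 76/19/51 — well inside the ±5-point recovery band the
tests use. P(expressed | none) = 0.10 is a chosen baseline leak rate
(the source percentages only cover the three enriched classes).

All randomness derives from one base seed through named substreams
(`substream_seed()`), one per (lineage, mark, replicate), per
randomization index, and per generator component — so adding a
replicate or permutation leaves all other draws untouched, and every
output is byte-reproducible from the configuration.

## Numerical and degenerate-input choices

* `hypothetical_maximum()` errors when `H ≤ 0` (the percentage sweep is
  undefined) and warns when the ratio SD is zero.
* A cutoff step that does not land on the minimum percentage appends
  the minimum as a final level with a warning.
* Levels with zero observed peaks get no FDR (`NA` in the level table);
  per-level FDR is capped at 1.
* `fisher_exact()` uses a relative tolerance of `1e-7` when comparing
  table probabilities to the observed one (standard practice to absorb
  floating-point ties in the probability-mass rule); zero-margin tables
  return p = 1 with a warning.
* MaxTen window means are computed by direct summation per window, so
  results are bit-identical to a naive reference implementation.
* Empty tracks yield empty peak sets; empty promoter classes are an
  error for metagene profiling (there is nothing to average).

## Problem sizes

The validation suite runs the full pipeline at 2,000 promoters × 2
lineages × 2 marks × 2 replicates (160,000 probe measurements), a
1,000-promoter pure-noise null, a 10-seed asymmetry suite at the truth
level, exhaustive Fisher enumeration for table totals ≤ 40, and
1,000-vector / 200-track brute-force oracle comparisons. These sizes
keep each statistical band (binomial 3·SE, ±5 percentage points,
±0.05 sharing) meaningful while the whole suite completes in about a
minute on one CPU.

## Known limitations

* The permutation scheme, cutoff step and probe layout reconstruct an
  unpublished vendor procedure; they are defaults, not assertions about
  the original software.
* Noise is spatially independent; autocorrelated probe noise would
  make the ≥ 4-probe window rule more permissive than the null
  simulation suggests.
* The generator does not model X-inactivation biology, so X-linked
  enrichment statistics are exercised on constructed sets, not planted
  signal.
* MaxTen averaging uses all provided replicates; analyses that averaged
  a fixed pair of replicates will differ slightly for N = 3 designs.
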