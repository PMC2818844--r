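# chromtile

Promoter chromatin-state analysis for ChIP-chip tiling arrays, built
for experiments that profile histone methylation (H3K4me3 and
H3K27me3) on promoter tiling designs — e.g. early embryonic lineages
(inner cell mass, trophectoderm) and embryonic stem cells — and ask
which promoters are active, Polycomb-repressed, or *bivalent*
(carrying both marks), and how those maps differ between lineages.

Inputs are probe-level log2 ChIP/input ratio tracks (one per
mark × sample × replicate) over promoters tiled from −2,000 to +500 bp
around the TSS. The package provides:

* **Peak calling with a randomization FDR.** Peaks are ≥ 4 probes above
  a cutoff within a 500-bp sliding window; cutoffs sweep 90%→15% of a
  *hypothetical maximum* `H = mean + 6·SD` of the track's ratios.
  Ratios are permuted across probe positions (20×) and
  `FDR(level) = mean permuted peaks / observed peaks`; each peak gets
  the FDR of its most stringent detection level.
* **Promoter scoring and classification.** MaxTen (highest mean of 10
  consecutive probe ratios, replicate-averaged) as a continuous score;
  enrichment calls requiring a peak at FDR ≤ 0.1 in 2 of 2 (or 2 of 3)
  replicates; four-way state none/K4/K27/bivalent.
* **Metagene profiles** anchored at the TSS (strand-oriented, 50-bp
  bins), including the "null-peak" background class.
* **Comparative statistics**: pairwise sharing fractions with Fisher's
  exact test, three-way Venn counts, X-linked fold enrichment, and
  percent-expressed per class from binary single-cell detection calls
  (present = detected in ≥ 10 of 20 cells).
* **A synthetic experiment generator** with planted per-lineage states,
  configurable cross-lineage sharing, replicate noise and a single-cell
  expression model, so the whole pipeline validates against ground
  truth without any external data.

Everything is tidyverse-shaped: functions take data frames and return
tibbles, results chain with the pipe, `tidy()`/`glance()` summarise
peak-calling runs, and `autoplot()` draws metagene profiles and
MaxTen scatters.

## Worked example

Simulate a 500-promoter two-lineage experiment, call peaks on one
H3K4me3 track, and classify ICM promoters:

```r
library(chromtile)

cfg  <- simulation_config(n_promoters = 500, seed = 1)
expt <- simulate_experiment(cfg)

pk <- call_peaks(expt$tracks[["ICM/H3K4me3/1"]], peak_call_params(seed = 1))
glance(pk)
#> # A tibble: 1 × 5
#>   n_peaks n_peaks_fdr_le_max hypothetical_maximum n_levels n_randomizations
#> 1     180                180                 3.41       16               20
```

180 peaks were detected on this track, all at FDR ≤ 0.1; the cutoff
sweep ran over 16 levels of `H = 3.41`. Classify promoters from both
marks' replicate peak calls:

```r
peaks <- lapply(expt$tracks, call_peaks, params = peak_call_params(seed = 1))
key   <- function(l, m) sprintf("%s/%s/%d", l, m, 1:2)
st <- promoter_state_table(
  peaks[key("ICM", "H3K4me3")],  peaks[key("ICM", "H3K27me3")],
  expt$tracks[key("ICM", "H3K4me3")], expt$tracks[key("ICM", "H3K27me3")],
  expt$promoters)
table(st$state)
#> bivalent      K27       K4     none
#>       65       83      114      238
```

The four states partition all 500 promoters. Cross-lineage K4 sharing
(after classifying TE the same way):

```r
ov <- overlap_counts(st$promoter_id[st$k4_enriched],
                     st_te$promoter_id[st_te$k4_enriched],
                     expt$promoters$promoter_id)
ov[, c("n_a", "n_b", "n_intersect", "sharing_a", "fisher_p")]
#> # A tibble: 1 × 5
#>     n_a   n_b n_intersect sharing_a fisher_p
#> 1   179   175         144     0.804 1.88e-59
```

80.4% of ICM H3K4me3 promoters are also H3K4me3-enriched in TE —
recovering the 0.80 sharing probability this simulation was configured
with. `autoplot(st)` draws the MaxTen scatter colored by state, and
`autoplot(metagene_profile(...))` the TSS-anchored profiles.

A YAML-driven end-to-end run (`run_pipeline(config, out_dir)`) writes
tracks, peak BEDs, per-level FDR tables, classification, metagene,
overlap and expression tables plus a checksum manifest; a thin CLI over
the same functions is installed at `inst/cli/chromtile`.

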