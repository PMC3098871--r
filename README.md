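# tilepeak

Transcription-factor target discovery from promoter tiling ChIP arrays and
expression time courses.

## The problem

ChIP-on-chip on promoter tiling arrays measures, for each promoter, a
handful of two-color probes (IP over mock-IP) spaced ~300 bp across
−2000..+800 bp of the TSS. Deciding whether a transcription factor such as
SMAD3 binds a promoter — and where, and how strongly — from 4–6 noisy
ratios per promoter needs a model of what a single binding event looks
like on the array. `tilepeak` implements that model-based caller together
with the downstream steps a TF-target study needs: motif-site scanning
with an empirically calibrated score cutoff, cyclic-loess normalization
and permutation testing of one-color expression time courses (with an
inhibitor arm such as SIS3), and the ChIP × expression integration with
Fisher's-exact gene-set enrichment. A synthetic-data module generates
every input with a machine-readable truth table, so the whole pipeline is
testable end to end with known ground truth.

## The model

Sonication yields fragments with length distribution *P(L)* (here 200–700
bp). A fragment of length *L* that covers the binding site covers a
position at distance *d* from it with probability max(0, 1 − |d|/L), so
the expected relative coverage of a single event is

    s(d) = Σ_L P(L) · max(0, 1 − |d|/L),

a symmetric, peaked curve with s(0) = 1 and support ± max L. The IP/mock
ratio of a probe at offset *x*, for an event at center *c* with fold
enrichment *f* over baseline *b*, is modeled as

    ratio(x) = b · ( 1 + (f − 1) · s(x − c) ).

The caller grid-searches *c* (25 bp steps) with a constrained
least-squares fit of (b, f) per candidate, and scores the peak against the
flat model with a variance-floored log-likelihood ratio
(k/2)·ln((rss0 + k·s0²)/(rss1 + k·s0²)), where s0² is the array-wide
median residual variance. Significance is an empirical p-value from
within-promoter permutations pooled across promoters (stratified by probe
count), with one refinement pass that removes likely-bound promoters from
the null pool. A gene is called bound when p < 0.01 in at least 2 of 3
replicates and the consensus peak height (fold enrichment) exceeds 1.5,
and ±100 bp around each called peak is extracted for motif scanning.

Motif cutoffs follow the background-sampling recipe: score *n* random
uniform-base sequences of the motif width with the log-odds matrix and
take the empirical (1 − α) quantile. Expression arrays are normalized by
cyclic loess on MA pairs, probes are averaged into genes, genes are
normalized to the 0 h baseline (log-scale geometric mean), and
differential expression is a permutation test on replicate label splits —
exact enumeration at n = 3 vs 3, with an optional pooled null across
genes for FDR-capable p-values.

## Worked example

```r
library(tilepeak)

layout <- generate_layout(200, seed = 1)            # 200 tiled promoters
shape  <- peak_shape(frag_dist_uniform(200, 700))   # event shape from shearing
print(shape)
#> Binding-event shape: s(0) = 1, half width 200 bp, support +/- 700 bp

truth  <- plant_chip_truth(layout, frac_bound = 0.1, fold = 3,
                           condition = "stimulated", seed = 2)
arrays <- simulate_chip_arrays(layout, truth, noise_sd_log2 = 0.1,
                               n_replicates = 3, seed = 3)
calls  <- call_condition(arrays, "stimulated", shape, B = 199, seed = 4)
head(calls[calls$passes, c("gene_id", "n_pass_reps",
                           "consensus_center", "consensus_height")], 3)
#>  gene_id n_pass_reps consensus_center consensus_height
#>    g0006           3             -300         2.524486
#>    g0017           3             -525         2.549890
#>    g0033           3            -1100         3.346509
```

`consensus_center` is the median fitted peak position (bp relative to the
TSS) across passing replicates and `consensus_height` the median fold
enrichment over the mock background. Against the planted truth this run
recovers every planted event with no false calls:

```r
bound <- truth$gene_id[truth$true_fold > 1]
mean(bound %in% calls$gene_id[calls$passes])          # sensitivity
#> [1] 1
mean(!(calls$gene_id[calls$passes] %in% bound))       # false-discovery prop.
#> [1] 0
```

A single promoter's fit reads directly as position and fold:

```r
g <- "g0006"
r <- subset(arrays, gene_id == g & replicate == 1 & condition == "stimulated")
fit_peak(r$offset_bp, r$ip_intensity / r$mock_intensity, shape)[c("center", "height")]
#> $center
#> [1] -225
#> $height
#> [1] 2.66       # planted: center -307 bp, fold 3
```

The full synthetic benchmark — peaks, motif fractions, normalization,
differential testing, integration, enrichment — runs with one call (or
`Rscript inst/cli/tilepeak.R run-all --seed 1 --out bench/`):

```r
report <- run_benchmark("bench", seed = 1)
```

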