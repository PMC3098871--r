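---
title: "Model-based promoter-array peak calling and TF-target integration: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based promoter-array peak calling and TF-target integration: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilepeak)
```

This vignette is the package's account of its statistical machinery: the
binding-event model, the significance calculus, the normalization and
testing of expression time courses, and the design choices made where the
problem left the design genuinely open. The synthetic-data module is
described last, together with what passing the test suite does and does
not establish about real arrays.

## The binding-event shape

Chromatin shearing produces fragments whose lengths `L` follow some
distribution on roughly 200–700 bp. A fragment is immunoprecipitated
because it contains the binding site; conditional on that, its placement
is uniform among placements covering the site, so it covers a position at
signed distance `d` with probability `max(0, 1 - |d|/L)`. Averaging over
the length distribution gives the expected relative coverage

$$ s(d) \;=\; \sum_L P(L)\, \max\!\left(0,\, 1 - \frac{|d|}{L}\right), $$

tabulated by `peak_shape()` at 1 bp resolution. `s` is symmetric,
decreasing, `s(0) = 1`, and vanishes beyond the longest fragment. The
default length distribution is uniform on [200, 700] bp
(`frag_dist_uniform()`); only the range is typically known from the
shearing protocol, so the shape within it is a free modelling choice, and
a truncated normal (`frag_dist_truncnorm()`) is provided as the obvious
alternative. For the uniform default the curve has a half width of 200 bp
— wide relative to the ~300 bp probe spacing, which is what makes
multi-probe coherence informative.

## Fitting one event per promoter

With probe offsets `x_i` and IP/mock ratios `r_i`, the single-event model
on the ratio scale is

$$ r_i \;\approx\; b\,\bigl(1 + (f - 1)\, s(x_i - c)\bigr), $$

with baseline `b > 0` and fold enrichment `f >= 1`. For each candidate
center `c` on an absolute 25 bp grid covering the probe span (anchored at
multiples of the step, so on-grid truths are recovered exactly), the model
is linear in `(b, a)` with `a = (f-1) b`, solved in closed form with the
constraints enforced by clamping (a negative slope or non-positive
baseline falls back to the flat model). Ratio-scale fitting makes the
reported height read directly as fold enrichment over the mock background.
Ties in residual sum of squares are broken toward the smaller `|c|`, then
the smaller `c`; numerically, candidates within `1e-9` relative RSS of the
minimum count as tied. The grid default of 25 bp is fine relative to probe
spacing and costs little at 2.8 kb spans. One event per promoter is
fitted — the dominant peak; deconvolution of overlapping events is out of
scope.

Degenerate inputs behave predictably: all-equal ratios give `f = 1` and
center 0 (the smallest-|c| grid point); fewer than 3 probes, non-positive
ratios, or an empty fragment distribution are errors.

## Significance: statistic and null

The classical nested-model statistic under homoscedastic Gaussian
residuals is `(k/2) ln(rss0 / rss1)` (`llr_statistic()`), where `rss0` is
the flat-model and `rss1` the peak-model residual sum of squares over `k`
probes. With `k` of only 4–6 and a grid of candidate centers, this
statistic is overfit-prone: on pure-noise promoters both residual sums are
tiny and their *ratio* is frequently enormous, which costs power exactly
where it matters. `call_condition()` therefore defaults to a
variance-floored version,

$$ \Lambda \;=\; \frac{k}{2}\,
   \ln\!\frac{rss_0 + k\,s_0^2}{rss_1 + k\,s_0^2}, $$

with `s0^2` the replicate-wide median of `rss1/(k-2)` — the same
moderation idea that small-sample microarray statistics use to stabilise
variance estimates. The floor leaves true peaks (whose `rss0` dwarfs
`s0^2`) essentially untouched while capping the noise-only ratios.
Permutation p-values are exactly valid for any choice of statistic, so
this is purely a power decision; `statistic = "ratio"` restores the plain
LLR.

The null distribution permutes ratio values across the probe offsets of a
promoter, preserving its marginal intensity distribution. A single
promoter's permutation space is tiny (at most 6! = 720 arrangements, and
the identity is always among them), so a per-promoter empirical p-value
(`empirical_pvalue()`) cannot reach below about 1/24 for 4-probe
promoters — far above a 0.01 calling threshold. The pipeline therefore
pools the permuted statistics across promoters within strata of equal
probe count, giving p-values with resolution `1/(B * n_genes + 1)`. Two
subtleties:

* **Pool contamination.** Truly bound promoters contribute peak-like
  permutations to the pool. One refinement pass removes promoters whose
  initial p falls below 0.05 from the pool and recomputes (skipped if more
  than half would be removed) — the usual empirical-null practice of
  estimating the null from apparently-null cases. The refinement makes the
  extreme tail mildly anti-conservative (the test suite measures the
  noise-promoter type-I rate at nominal 0.05 and checks it stays within
  0.03–0.07, and the Kolmogorov–Smirnov uniformity of null p-values),
  which is the accepted price for not letting signal inflate its own null.
* **An array-wide shuffle was rejected.** Shuffling ratios across all
  probes of the array spreads the bound promoters' elevated ratios into
  every null draw, which fattens the pooled tail much more than
  within-promoter permutation does; it is not offered.

A gene is called bound when its p-value is below `p_thresh` (default
0.01) in at least `min_reps` (default 2) replicates and its consensus
height — the median across passing replicates — exceeds `height_thresh`
(default 1.5, fold units). The height filter applies to the consensus
rather than per replicate, reading the event definition as a per-event
criterion once replicate support is established; the replicate rule is
applied first, then the consensus, then the height filter. For genes with
no passing replicate the consensus falls back to the median across all
replicates so that binding-change rankings are defined everywhere; such
genes never pass. `±100` bp around each called center is extracted
(truncated and flagged at sequence ends) for motif work.

## Motif scanning

Matrices are position frequency matrices over A, C, G, T (TRANSFAC count
and UniPROBE probability dialects are parsed), scored as log-odds against
a uniform background with pseudocount 0.01:
`ln((f + pc) / (1 + 4 pc) / 0.25)`. "Uniform distribution" in the cutoff
calibration is read literally as uniform base composition: the cutoff is
the empirical `(1 - alpha)` quantile (inverse-ECDF order statistic) of the
scores of `n_samples` random width-length sequences. Scanning covers both
strands (the minus strand via the reverse-complemented matrix), skips
windows containing N, and uses a `1e-9` tolerance at the cutoff so that
windows scoring exactly at threshold are treated identically on both
strands despite summation-order float jitter.

One quantitative caveat matters for region-level claims. A 201 bp
dual-strand region contains ~388 windows, so at the per-window
`alpha = 0.05` of the classical recipe the family-wise chance of at least
one hit is essentially 1 — *every* region is a "hit" for *any* matrix,
and a fraction-of-bound-regions-with-motif statistic saturates. The
planted-fraction experiments in this package therefore calibrate a
stringent per-window cutoff (`alpha = 5e-5` from 2×10⁵ samples), putting
the per-region chance-hit rate near 2%, so that a 70% planting rate is
recovered as a ~70% hit fraction above a measured, small null inflation.
When comparing against fractions computed with a permissive per-window
alpha, this inflation must be kept in mind.

## Expression time courses

Arrays are background-subtracted single-channel intensities, log2
transformed. Cyclic loess normalization fits, for every pair of arrays, a
degree-1 loess of `M = log2(x_i) - log2(x_j)` on `A = (log2(x_i) +
log2(x_j))/2` over a once-drawn random subset of 5000 probes, predicts the
curve for all probes (prediction clamped into the fitted A range), and
moves each array of the pair half the curve toward the other; a cycle
visits all pairs, and iteration stops when the maximum absolute
adjustment in a cycle falls below epsilon.

Two numerical facts shaped the defaults. First, the span: at span 0.4 the
fits are flexible enough to chase probe-level noise and the cyclic updates
oscillate without settling; span 0.7 contracts cleanly. Second, epsilon:
the stopping statistic is a *maximum* over all pairs and probes, so it has
a sampling floor set by the loess fit's own variability — about 0.01–0.03
log2 at a 5000-probe subset with realistic probe noise. The default
epsilon 0.02 sits at that floor: on dye-bias-only data normalization then
stops after two or three cycles (the acceptance suite checks ≤ 5, and —
more substantively — that a fresh M~A loess on normalized arrays is flat
to 0.05 against a planted bias of amplitude 0.3). Demanding epsilon below
the floor makes "convergence" a property of the noise draw, not of the
data. Note also that when a large fraction of genes carries genuine
differential signal, the pairwise M~A structure is partly real and the
max-change plateaus above the dye-bias floor; stopping is then governed by
`max_iter` and the convergence flag reports honestly.

Probes are averaged into genes on the log2 scale; gene rows are then
normalized per arm to the mean 0 h log2 value (the log-scale equivalent of
dividing by the geometric mean of the 0 h replicates), making the
pipeline invariant to per-array rescaling up to loess edge effects.

Differential testing between two timepoints uses the mean-difference
statistic under replicate-label permutation. With 3 + 3 replicates all 20
splits are enumerated; the two-sided exact p-value is the fraction of
splits at least as extreme, so its granularity is 0.1 — which means
per-gene BH control at FDR 0.1 can never reject. The pipeline-level test
(`de_test_timepoint()`) therefore pools split statistics across genes
(assuming comparable per-gene noise scales, which holds for the generator
and approximately for normalized arrays), with the same one-pass
refinement of the pool as in peak calling. Pooled p-values have resolution
`1/(20 · n_genes)` and support FDR control; the refinement again trades a
mild tail anti-conservatism (realized false-discovery proportions can
exceed the nominal BH level under dense strong signal) for power. The
per-gene exact test remains available and untouched. Bonferroni and BH
corrections are delegated to `stats::p.adjust`; ΔΔCt relative
quantification is the standard `fold = 2^-((ΔCt_treated) - (ΔCt_control))`.

## Integration and enrichment

The integrated table is a lossless outer join of basal and stimulated
consensus heights with replicate-averaged expression log2 ratios per
(arm, timepoint); the binding change is `height_stimulated -
height_basal`, rows are ranked by it (NA last, ties by gene id), and
`top_k()` takes the conventional top-57 slice deterministically. The
binding index used for ranking is this stimulated-minus-basal consensus
height — the natural reading where no formal definition exists.
Enrichment is the one-tailed hypergeometric upper tail
`P(X >= overlap)` per gene set (`stats::phyper`; the test suite checks
agreement with `stats::fisher.test` to 1e-10 relative), with the pathway
ratio `overlap / |set|` after intersecting sets with the universe. The
universe defaults to the genes on the promoter array — the defensible
stand-in for a proprietary knowledge-base universe. Combined
ChIP+expression enrichment is expressed as separate tests of the
ChIP-only, expression-only and common gene lists.

## The synthetic-data module

The generator is first-class, tested code, and its defaults are the study
conditions exercised throughout: promoters tiled by 4–6 probes on a
jittered 300 bp grid (consecutive spacings 250–350 bp) within −2000..+800
bp; fragment lengths uniform on 200–700 bp; planted binding events
entering the two-color forward model `ratio = 1 + (f-1) s(x-c)` with
multiplicative log-normal noise (sd 0.1 log2 per channel) applied
independently per probe, replicate and channel, and a common mock
background; 10% of promoters bound at fold 3 in the stimulated condition;
promoter sequences at 50% GC with consensus motif instances planted at
recorded positions (consensus rather than matrix-sampled instances, so a
planted region is a true positive by construction — sampled instances of
even a sharp matrix fall below stringent cutoffs at a material rate);
expression with gene baselines N(8, 1.5²) log2, probe affinities
N(0, 0.3²), 3 replicates × {0, 2, 12, 24 h} × {vehicle, SIS3}, planted
|log2| = 1.5 effects in 10% of genes, SIS3 retaining 20% of the effect by
default, smooth per-array quadratic intensity-dependent bias of amplitude
0.3 log2, and probe noise 0.25 log2. All generators are bit-reproducible
under a fixed seed, and every planted signal is enumerated in a truth
table.

What the generator does **not** emulate: probe-sequence affinity biases
correlated with composition, spatial array artifacts, scanner saturation,
cross-hybridization, partial fragment pulldown, or correlated noise
between channels. Passing the recovery tests therefore shows the
algorithms invert their own forward model under realistic noise levels —
it bounds implementation error, not biological error on real arrays,
where the event shape, background and noise structure are all less clean.

## Problem sizes and runtime choices

The shipped checks run at: 10⁶ fragments for the shape oracle; 100 random
configurations for noiseless inversion; 1000 pure-noise promoters at
B = 199 for null calibration; 500 promoters (10% planted, 3 replicates,
B = 199) for end-to-end recovery; 10⁴-sample cutoffs checked against full
enumeration for widths ≤ 8 and a 200-promoter planted-fraction
experiment; 2000-gene dye-bias normalization; 1000-gene permutation
calibration; and a 500-gene expression benchmark. These sizes give
Monte-Carlo errors comfortably inside the asserted tolerances while
keeping the whole suite fast.

## Known limitations

* One event per promoter; overlapping events bias center and height.
* The pooled permutation nulls assume exchangeable noise across promoters
  (respectively genes) within a stratum; strong heteroscedasticity across
  promoters would call for finer stratification.
* The pool-refinement pass makes extreme-tail p-values mildly
  anti-conservative; at dense strong signal, realized FDP exceeds the
  nominal BH level.
* Ratio-scale least squares is unweighted; multiplicative noise makes
  high-ratio probes noisier, so heights at large folds carry more
  variance than a weighted fit would give.
* The motif cutoff calibrates against uniform base composition; GC-biased
  backgrounds shift the effective per-window alpha.
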