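---
title: "SpliceStage: models and methods for developmental splicing analysis"
author: "SpliceStage authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SpliceStage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

During brain development, hundreds of cassette exons switch their inclusion
level (percent spliced in, PSI) in a tightly timed fashion: one wave of
switches completes around birth, a second wave during the first two
postnatal weeks. SpliceStage implements the analysis toolkit for this
biology: quantifying PSI from splice-junction reads, detecting temporal
co-splicing modules, timing each exon's switch with a sigmoidal model,
staging any transcriptome sample against a developmental reference, and
locating the biological functions that turn over at each developmental
moment. A seeded synthetic-data generator reproduces the statistical
structure of a nine-time-point developing-cortex reference so that every
step can be exercised and validated without external data.

# PSI quantification and differential splicing

A cassette exon's inclusion isoform spans two exon--exon junctions while the
skipping isoform spans one. To put the isoforms on the same scale the raw
inclusion-junction count is halved: `i = inc_reads / 2`, coverage
`c = i + skip_reads`, and `PSI = i / c`. The halving convention is exposed
as `halve_inclusion` in `estimatePsi()` and `fisherDiff()` because junction
tables from other pipelines sometimes pre-average the two inclusion
junctions.

Two filters drop unreliable estimates: effective coverage below `min_cov`
(default 20 reads) and a binomial standard deviation
`sqrt(PSI (1 - PSI) / c)` at or above `max_sd` (default 0.1). Both defaults
are the standard working values for bulk-brain junction data. Zero-coverage
cells are missing, never `0/0` errors, and a PSI of exactly 0 is a real
observation, distinct from missing; on disk, missing cells are empty
strings in the TSV, never zeros.

Differential splicing between two conditions pools replicate counts per
condition (explicit replicate modeling is out of scope), rounds the halved
inclusion counts half-to-even, and applies the standard two-sided Fisher's
exact test to the 2x2 (inclusion, skipping) x (condition A, B) table; the
two-sided p-value is the sum of the probabilities of all tables with the
same margins that are no more probable than the observed one, ties
included. Benjamini-Hochberg correction runs across exons (ties in p get
equal q; the output order matches the input). An exon is called at coverage
>= 20 in both conditions, FDR <= 0.05 and |dPSI| >= 0.2. Over a series of
ordered developmental stages, an exon is *developmentally regulated* if
called in at least one pairwise comparison and *monotonic* if every
significant change has the same sign.

# Temporal modules

Module detection follows the weighted-correlation-network recipe on the
exon x time-point PSI matrix (complete rows only):

1. adjacency `a_uv = |pearson(u, v)|^3` (unsigned; the cubed soft
   threshold suppresses weak correlations while keeping the network
   connected). A signed variant `((1 + r)/2)^3` is available via
   `signed = TRUE`, but the unsigned default reproduces the natural
   presentation in which each module carries a `+` and a `-` half with
   mirrored trajectories;
2. topological-overlap dissimilarity, which rewards shared network
   neighborhoods and is more robust than raw correlation distance;
3. average-linkage hierarchical clustering;
4. a static cut. Dynamic tree cutting is deliberately not reimplemented;
   instead the default cut height is chosen deterministically as the
   greatest height that maximizes the number of clusters reaching
   `min_size` (default 30 exons), scanned over the midpoints between
   consecutive dendrogram merge levels. On planted-module data this lands
   between the within-module and between-module join levels; a fixed
   `cut_height` can be supplied to override it. Average linkage on
   topological overlap occasionally produces tiny height inversions, which
   `cutree()` rejects; cutting therefore uses a monotonicity-enforced
   (cummax) copy of the merge heights, which preserves the merge order;
5. an eigenexon per module: the first principal component of the
   standardized (per-exon centered and scaled) member profiles, unit norm,
   oriented so its mean correlation with the member profiles is
   non-negative (ties fall back to making the first non-zero entry
   positive, so the result is fully deterministic and invariant to exon
   order);
6. iterative merging: while any two eigenexons have dissimilarity
   `1 - cor < 0.25` (the conventional default), the closest pair is merged
   and the eigenexon recomputed. Merging the closest pair first makes the
   result independent of module enumeration order. Curated merges are
   available through `force_merge`.

Modules are labelled `M1, M2, ...` by decreasing size. Each member's
correlation with its module eigenexon gives its sign (`+`/`-`) and its
core status: core members have `|r|` at or above the critical correlation
whose two-sided p-value (t transform, `n - 2` degrees of freedom) equals
`alpha = 0.001`. With nine time points this threshold is ~0.898, i.e.
approximately 0.9.

# Switch timing

Each exon's trajectory is parameterized as

    PSI(t) = a + (k - a) / (1 + exp(-b (t - m)))

with `a`/`k` the low/high inclusion levels, `b` the slope (sign = switch
direction), and `m` the switch midpoint. Time is log10 post-conception
days: embryonic day labels are used directly (E14.5 -> 14.5 days), postnatal
days are shifted by the 19.5-day mouse gestation (P0 -> 19.5), and months
count 30.44 days (both constants are arguments of `toLog10Pcdays()`). The
log scale reflects that developmental tempo slows roughly geometrically
with age.

Fitting is bounded nonlinear least squares (the `port` algorithm, with a
bounded quasi-Newton fallback if `nls` fails to evaluate): `a, k` in [0, 1],
`m` within the observed time range widened by 0.5 log10-days, `|b| <= 200`.
Because the objective is multimodal in `m`, five starts are used: `m` at
the trajectory's half-range crossing and at the quartiles of the time axis,
each with `b = +-4`; the smallest residual sum of squares wins. The fitted
parameterization is normalized to `a <= k` (swapping `a`/`k` while negating
`b` is an exact identity of the model), so direction lives entirely in
`sign(b)`.

Fit quality is the normalized residual

    epsilon = sqrt( sum_i (PSI_i - fit_i)^2 / (N (k - a)) )

with `N` the number of non-missing time points (missing stages simply drop
out). A fit is *reliable* when `epsilon < 0.15`, `k - a > 0.2` and `m > 0`;
a degenerate range (`k = a`) yields `epsilon = Inf` and can never be
reliable. Reliable fits, ranked by ascending `m` with ties broken by exon
id, form the switch-time ranking used downstream.

# Maturation staging

The staging model treats a query sample's module-exon PSI vector `y` as
beta distributed, `y_i ~ Beta(mu_i, phi)` in the mean/precision
parameterization (`var = mu (1 - mu) / (1 + phi)`), with

    logit(mu_i) = sum_j x_ij beta_j

where `x_ij` is exon `i`'s inclusion in reference time point `j`. There is
no intercept: the printed model projects the query into the subspace
spanned by the reference columns, and an intercept would let the fit drift
off that subspace (a flag exists for robustness experiments). The beta
likelihood is the right noise model for a (0, 1)-bounded response with
precision increasing away from 0.5.

Numerics: boundary observations break the beta density, so `y` is shrunk by
`(y (n - 1) + 0.5) / n` with `n` the number of exons used -- deterministic
and asymptotically negligible. Coefficients are initialized by least
squares of `logit(y)` on the reference columns and `phi` by method of
moments; optimization is BFGS on `(beta, log phi)` with analytic gradients
and up to three damped restarts. Only exons observed in the query and
complete across the reference enter the fit, with a floor of `min_exons`
(default 50; below that the projection is too unstable to report and the
function errors instead).

One consequence of the logit link worth knowing: the projection is a
monotone transform of the reference profiles, not the identity, so even a
reference column run as its own query reproduces itself only approximately
per exon. What the model guarantees -- and what the tests assert -- is the
ordering: the projected column is closer to itself than to any other
reference sample.

Distance to each reference sample is the squared Euclidean distance

    D_j = sum_i (x_ij - mu_hat_i)^2

reported exactly in that (unrooted) form. The stage is assigned by the
1-nearest reference sample; all reference ages at or after P15 share the
terminal stage because post-P15 profiles are nearly indistinguishable
(stage maps are part of the `ReferenceAtlas` and user atlases may define
their own). Distance ties break toward the younger stage -- the
conservative direction for maturity claims. Confidence is
`S = 1 - min(D) / max(D)`: 1 for a perfect match, 0 when all references are
equally distant (an explicit warning case). PCA coordinates (components
fitted on the reference columns only, queries projected with
reference-mean imputation of missing exons) are attached for display and
never influence the stage call.

Restricting the exon universe to the direct targets of one RNA-binding
protein family stages the sample by that regulator's program alone; the
subset label is recorded in the prediction.

# Enrichment analyses

All enrichment uses the upper-tail hypergeometric test. The sliding-window
scan ranks exons by switch time and advances a 300-exon window one rank at
a time (`floor((L - window)/step) + 1` windows); each window's deduplicated
gene set is the foreground, all catalog genes the background. Correction is
Benjamini-Hochberg *jointly across every (term, window) pair* -- per-window
correction would overstate significance for terms that persist across many
overlapping windows -- at a strict default FDR of 0.005 (the figure-level
convention of 0.05 is one flag away). Terms with fewer than 5 background
genes are not tested (degenerate hypergeometric tails). Per-module
enrichment uses the same machinery with each module's core exon genes as
foreground at FDR 0.05. Significant terms' `-log10(FDR)` profiles across
windows are grouped by average-linkage hierarchical clustering on Euclidean
distance, with terms sorted beforehand so leaf order is reproducible.

Hexamer enrichment compares flanking intronic sequence sets (conventionally
200 nt per region) by presence/absence per sequence -- the counting model
that actually matches hypergeometric sampling, unlike total occurrence
counts -- across all 4096 hexamers, skipping windows containing non-ACGT
letters, with BH correction across hexamers. The background is expected to
contain the foreground.

# The synthetic generator

`simulateReference()` emulates the structure the pipeline assumes, not raw
sequencing: exons are assigned to modules (`module_mix` defaults: 30% M1,
30% M2, 5% M3, 5% M4, 30% null), each with a planted trajectory on the
nine-age axis E14.5 ... 21 months:

* **M2 (early)**: sigmoid midpoint at birth, `m ~ Normal(t(P0), 0.02)`;
* **M1 (late)**: midpoint uniform between P7 and P15;
* **+/- halves**: mirrored switch directions within M1 and M2;
* **M3/M4**: sums of an early and a late sigmoid of opposite sign, giving
  the up-then-down / down-then-up composites of two independent regulatory
  events;
* **null**: flat trajectories at a uniform level.

Switch levels are `a ~ U(0.02, 0.25)`, `k ~ U(0.75, 0.98)`; slopes are
`|b| ~ U(20, 50)`, i.e. a switch completes over roughly 0.1--0.2 log10-days
(a few days around birth) -- sharp enough that the early and late programs
are temporally distinct on the nine-point axis, as developmental switches
are. Noise is two-level: reflected-Gaussian perturbation of the trajectory
(biological variability, default SD 0.05) followed by binomial read
sampling at negative-binomial per-cell coverage (counting noise, default
mean 100, size 5). The reference atlas covers the module exons only, as a
real module catalog would. Queries are drawn at any age in the reference
range; "sensory-like" queries freeze the early program at its most
immature values while the late program sits at adult values.

What the generator does **not** emulate: read-level artifacts (mapping
bias, positional coverage), exon-exon dependence within a gene,
drop-out structure of single-cell data, and annotation errors. Passing
tests therefore demonstrate correctness of the statistical machinery under
the stated model, not robustness to those artifacts.

A structural note on chimeric profiles: when a query hard-freezes the early
program at immature values and the late program at adult values, the
squared-distance curve across reference ages is U-shaped (interior
references mismatch both programs), so the full-profile 1-NN stage lands at
one end rather than in the middle -- exactly as observed for real sensory
neurons, whose full-profile predictions are extreme stages while
subset-based staging exposes the dissociation. Subset staging, not the
full-profile call, is the instrument for detecting chimeric maturity.

# Problem sizes and determinism

The test suite validates parameter recovery on 200 read-sampled exons
(median switch-time error under 0.1 log10-days at coverage 100), staging on
100 seeded queries (>= 90% exact, >= 99% adjacent), module recovery on
1,000 exons at noise SD 0.05 (>= 90% membership agreement), and
false-discovery control of the window scan over 100 seeded null runs --
sizes chosen so the full suite runs comfortably on a laptop while keeping
every estimate's sampling error far from its acceptance margin. Every
stochastic component takes an explicit seed and restores the caller's RNG
state, so all results are bit-reproducible.
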