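---
title: "Methods: inferring genomic fingerprints of soil microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring genomic fingerprints of soil microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilfp)
```

## The problem

Soil metagenome compilations summarize each sample as a vector of attribute
counts — KEGG orthologies, Pfam or TIGRFAM protein families, or read-based
genus assignments. Most attributes are either nearly ubiquitous (central
metabolism) or too rare to carry signal, and raw counts are confounded by
sequencing depth and by compositional effects. `soilfp` distils such tables
into *genomic fingerprints*: small, signed attribute sets associated with
high or low values of a soil factor (bulk density, CEC, nitrogen, pH, SOC,
clay), with a biome, or with an emergent cluster of samples.

## Data model and assumptions

An attribute table is samples × attributes with non-negative counts; a
strict TSV dialect (first column `sample`, samples in rows) is enforced
rather than auto-detected, because silent transposition is a classic
tabular-omics failure. Metadata may be missing per cell: samples missing
the factor under study are dropped for that analysis only, since each
factor is analysed independently and a global drop would discard usable
samples from unrelated analyses.

## Filtering and normalization

Two filters precede normalization:

* **Sample depth** (strict `>`): 2000 total reads for KO and Pfam, 500 for
  TIGRFAM (read counts run systematically lower in that annotation set),
  4000 for genera.
* **Attribute retention** (inclusive, logical OR): non-zero in at least
  `ceiling(n/2)` samples, *or* total count ≥ 7560. The constant corresponds
  to an average of 5 reads per sample over 1512 samples;
  `derive_min_total_count(reads_per_sample, n_samples)` generalizes the
  arithmetic to other data sizes. The prevalence denominator is the
  post-sample-filter count, and the half is rounded up — a deterministic,
  conservative reading.

Normalization is trimmed mean of M-values. The reference sample is the one
whose 75th-percentile count fraction is closest to the mean across samples.
Per sample, log2 fraction ratios (M) and mean log2 fractions (A) are formed
over attributes positive in both sample and reference — pairwise zero
exclusion, no pseudocounts — then double-trimmed (30% per side on M, 5% per
side on A, the canonical defaults of the method, exposed as `tmm$trim_m` /
`tmm$trim_a`) and averaged with inverse approximate binomial variances as
weights. Factors are rescaled to geometric mean 1. A sample whose M-values
are all below 1e-6 in magnitude (a pure depth rescaling of the reference)
gets factor exactly 1. Normalized values are counts per million over the
effective library size (raw total × factor); whether downstream statistics
should see CPM or library-scaled counts is not dictated by the method
itself, and CPM was chosen because it keeps values comparable across
samples of very different depth. Note that the precision weights depend on
absolute counts, so TMM factors are only asymptotically invariant to
rescaling a single sample's counts; tests assert this at 1e-3.

## Breakpoint segmentation

Sorted importance, abundance, and coefficient-of-variation curves are cut
by least-squares piecewise-constant segmentation: exact dynamic programming
over all admissible break positions, with minimum segment length
`max(min_segment, ceiling(h n))` (`h = 0.01`, `min_segment = 2`). The
number of breaks is selected by BIC,
`n log(RSS_b/n) + (2b + 1) log n` (one mean per segment plus one position
per break). Zero-RSS segmentations are floored at `RSS_0 × 1e-10` so the
criterion stays defined; because the floor scales with the data, selection
is invariant to adding a constant and equivariant under positive scaling.
A constant series, or one too short for any admissible break, yields zero
breakpoints (an empty fingerprint head with a warning), not an error.

The *fingerprint cut* uses a two-regime segmentation (`breakpoint$max_breaks
= 1` in `fp_config()`): the single optimal break separates the leading set
from the tail. This was a genuinely open design point. With multi-break BIC
selection on a smoothly decaying curve, the extra breaks land *inside* the
leading region — the steepest part of an exponential decay is where
piecewise-constant means gain the most — so a "first segment" rule would
shrink the head to the top few attributes even when the signal/noise cliff
sits much lower. The two-regime cut puts the break on the cliff itself,
which is the quantity of interest: one set of leading attributes against a
background. `segment_series()` remains fully general (any `max_breaks`) for
exploratory use, and its dynamic program is verified against exhaustive
enumeration in the test suite. One consequence worth noting: with a minimum
segment length of 2, a head of size 1 is inadmissible, so a single
overwhelmingly dominant attribute yields a two-element head rather than a
singleton.

## Supervised fingerprints

For a factor, the contrast groups are the lowest and highest
`floor(0.10 n)` samples (ties broken by a stable sort on value then sample
id, making the split deterministic and the direction assignment exactly
antisymmetric under factor negation). A permutation-importance random
forest (500 trees, single-threaded, seeded; importance = mean decrease in
out-of-bag accuracy divided by its standard error) ranks all attributes;
the ranking is descending with ties broken by attribute id. After the
breakpoint cut, each head attribute's normalized abundance is regressed on
the factor **over all usable samples**, not only the extreme deciles — the
extremes define what is important, the full gradient defines direction and
effect size. Members are signed by OLS slope; zero-variance attributes are
excluded and a zero slope leaves an attribute unassigned.

Biomes are fingerprinted one-vs-rest with a binary indicator regression
for the sign, which matches reporting fingerprints per biome with positive
and negative associations; a multi-class importance model is available by
passing the biome label vector to `rank_importance()` directly. The 10%
split fraction cannot apply to categorical biomes, so the one-vs-rest
labelling is the only consistent grouping.

## The model-quality gate

`cross_validate()` z-scores the response over all usable samples (factors
have incommensurable units — pH vs. g/kg SOC — so an RMSE threshold is only
meaningful on a standardized scale; every report flags
`standardized = TRUE`). Per repeat (5 total), samples are split 50/50; a
10-fold cross-validation inside the training half selects the forest's
feature-subsampling width `mtry` over the standard three-point grid
`floor(seq(2, p, length.out = 3))` — repeated k-fold CV around a forest is
the conventional way to set this width, and an untuned square-root default
systematically under-fits responses encoded by few attributes — and the
gate statistics come from the held-out half. The gate passes when RMSE
< 0.8 **or** variance explained ≥ 0.60 ("and/or" read literally as OR; an
AND policy is available in config). Gated-out factors yield no fingerprint.

## Unsupervised fingerprints

k-means runs on standardized `log1p` CPM features (raw CPM scales would let
a few abundant attributes dominate Euclidean distances); constant features
are dropped. k is scanned over 2–12 (clusters beyond 7 appear in practice,
so the scan extends comfortably past that) with 10 restarts per k, on a
canonically sorted sample order so the solution is invariant to input row
order; cluster ids are relabelled by first occurrence. The chosen k
maximizes mean silhouette; the elbow (total within-SS) curve is reported
alongside rather than folded into the choice, because the silhouette gives
a single interpretable optimum while the elbow is a diagnostic.

Per cluster, the per-sample **total** normalized abundance — the sum over
all retained attributes, not only cluster-defining ones — is regressed on
each factor; significance is assessed at α = 0.05 without multiplicity
correction (exposed in config; the selection statistic is a count of
significant factors, not an inferential claim). Clusters with fewer than 3
samples are unusable; factors constant within a cluster are skipped. The
selected cluster maximizes the significant-correlation count, ties broken
by mean R² over significant factors. Whether even the best cluster is
*informative* is decided by a configurable minimum count
(`unsupervised$min_significant`, default 3); an uninformative solution is
flagged, mirroring attribute types that yield no satisfactory model, but
its statistics are still reported. The abundant/variable fingerprints are
breakpoint heads of the within-cluster total-abundance and CV curves
(CV = sd/mean over the cluster's samples; zero-mean attributes excluded, so
constant attributes can never lead).

## The synthetic generator

`generator_spec()` states the generative model in full, since the data it
emulates assume nothing explicit: log-normal baseline attribute weights
(meanlog log 100, sdlog 1), multiplicative planted effects
`exp(effect_size (u − 0.5))` where `u` is the factor scaled to its range —
so `effect_size` is the natural-log fold change across the observed factor
range, default 2 — compositional closure per sample, log-normal library
sizes (expected 2e5 reads, sdlog 0.5), and negative-binomial counts with
overdispersion 0.2 (variance `μ + 0.2 μ²`; 0 gives Poisson). Factor ranges
default to the observed ranges of the six soil variables in the reference
compilation (e.g. pH 4.4–8.3, SOC 2.4–510.9 g/kg). Defaults plant 20 rising
and 20 falling attributes for one factor among 500 background attributes in
300 samples — sized so end-to-end recovery runs are a matter of seconds to
minutes.

The fertile-cluster scenario assigns a latent fertility gradient
`f ~ U(0, 1)` to a 25% sample subset: SOC, N, and CEC rise with `f` while
bulk density and clay fall (scaled-position offsets ±0.4 f with sd 0.03
noise), and 25 designated attributes are multiplied by
`exp(log 6 + log 3 · f)` on a baseline shifted 1.5 log units above
background with a quarter of the background spread. The separation
parameters were set so the designated set forms a contiguous block at the
top of the within-cluster abundance curve — that *is* the scenario being
modelled (a designated most-abundant set); with weaker separation the
background log-normal upper tail interleaves with the weakest planted
attributes and the scenario no longer embodies its own definition. The
within-cluster fertility gradient is what couples total normalized
abundance to the factors: the planted set dilutes the background
composition in proportion to `f`, the TMM factor absorbs the dilution, and
the per-sample total (1e6 / factor) rises with fertility.

What the generator does **not** emulate: phylogenetic correlation among
genera, spatial autocorrelation, biome-conditional factor distributions,
annotation noise, or the heavy inter-study heterogeneity of real
compilations. Passing recovery tests therefore demonstrate that the
pipeline's machinery is correct and well-calibrated under its stated
model — not that real soil compilations will yield fingerprints of
comparable purity.

## Numerical choices and degenerate inputs

* Determinism: every stochastic step (generator, forests, CV splits,
  k-means restarts) derives its seed from a single user seed;
  forests run single-threaded. Same-seed runs are bit-identical.
* Tie-breaks: decile membership by (value, sample id); importance ordering
  by (importance desc, attribute id); abundance/CV ordering by (statistic
  desc, attribute id); silhouette ties by smallest k; cluster-selection
  ties by mean R².
* Degenerate inputs fail loudly and specifically: all-equal factor values
  (no extremes), zero-variance responses, samples sharing no positive
  attributes with the TMM reference, disjoint sample sets, empty
  post-filter tables. Empty fingerprint heads are warnings, not errors.
* Test and acceptance runs use scaled problem sizes chosen as the
  package's reference conditions: 300 × 540 for supervised recovery (5
  seeds), 200 × 130 for gate behaviour (5 seeds), 300 × 525 for
  fertile-cluster recovery (10 seeds); smaller variants exercise unit
  behaviour.

## Known limitations

* TMM assumes most attributes are not differentially abundant between
  samples; extreme compositional shifts (as in the deliberately strong
  fertile scenario) are absorbed into the factors, which is what couples
  cluster totals to the environment here, but factors should not then be
  read as pure depth corrections.
* Permutation importance shares credit between correlated attributes; a
  duplicated informative attribute stays in the top ranks but individual
  importances shrink.
* The two-regime fingerprint cut returns one leading set by construction;
  curves with genuinely nested regimes (e.g. a handful of dominant
  attributes above a broader signal shelf) are summarized by the outermost
  cliff only.
* The gate's OR combination is permissive: a factor can pass on RMSE alone
  with modest variance explained near the threshold.
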