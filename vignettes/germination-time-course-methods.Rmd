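---
title: "Methods: time-course microarray analysis of seed germination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-course microarray analysis of seed germination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatgerm)
```

`wheatgerm` implements a complete analysis chain for short expression
time courses of the kind used to profile wheat seed germination on
Affymetrix-style arrays: five stages at 0/12/24/36/48 hours after
imbibition (HAI), three biological replicates per stage, one array per
replicate. This vignette explains each stage's model, its tunable
parameters, and the design choices made where the published
methodology leaves the details open.

## Probe-set summarization

Probe sets carry 11 perfect-match/mismatch (PM/MM) probe pairs. The
summarizer follows the MAS 5.0 sketch:

* **Background** — the mean of the lowest 2% of all feature
  intensities on the array. The original algorithm splits the array
  into 16 zones and distance-weights the zone backgrounds; since probe
  coordinates are not part of our data model, we use a single zone
  with uniform weights (`estimate_background()`). Background-corrected
  intensities are floored at 0.5.
* **Ideal mismatch** — MM itself when MM < PM; otherwise
  `PM * 2^-max(SB, 0.03)` where SB, the specific background, is the
  one-step Tukey biweight of `log2(PM/MM)` over the probe set's
  informative pairs. The floor of 0.03 log2 units keeps the ideal
  mismatch strictly below PM, so `PM - IM` stays positive (values are
  nevertheless floored at `2^-20` before taking logs).
* **Signal** — `2^biweight(log2(PM - IM))`, with the one-step Tukey
  biweight at tuning constant `c = 5` and an `1e-4` guard on the MAD
  denominator. One step (not iterated) matches the usual whitepaper
  convention for this estimator.
* **Detection call** — a one-sided Wilcoxon signed-rank test that the
  discrimination scores `R = (PM - MM)/(PM + MM)` exceed `tau = 0.015`;
  p < 0.04 is Present, p < 0.06 Marginal, otherwise Absent.
* **Scaling** — each array is multiplied by one factor so its
  2%-trimmed mean equals 500, making arrays directly comparable.

## Differential expression: RVM-moderated ANOVA

Genes are tested with a one-way ANOVA across the five stages on the
log2 scale. With three replicates the per-gene variance estimate is
noisy, so it is moderated under a random variance model: reciprocal
gene variances are assumed gamma-distributed with shape `a` and scale
`b`, which implies the observed residual variance satisfies
`s^2 * a * b ~ F(df, 2a)`. The hyperparameters are fitted once per
dataset by numerical maximum likelihood of that scaled-F density
(`fit_rvm_hyperparams()`), and each gene's denominator becomes

```
s2_tilde = (df * s2 + 2/b) / (df + 2a)
```

with the moderated statistic referred to `F(k - 1, df + 2a)`. As `a`
grows the prior dominates and the statistic converges to the
pooled-variance F; the fit is refused outright when all variances are
identical, since the shape is then unidentifiable.

The false discovery rate is estimated by permutation: array labels are
permuted freely across groups (a global-null permutation), the
moderated statistics recomputed with the same hyperparameters, and at
each observed statistic t

```
FDR(t) = mean permuted count of F >= t / observed count of F >= t
```

clipped to [0, 1] and made monotone non-increasing in t by letting
each gene take the smallest ratio achievable at any weaker threshold.
"≥" is applied inclusively on both sides so ties are handled
symmetrically. The published protocol used 1,000 permutations, which
remains the default; tests and the acceptance script use 200, where
the FDR estimates are already stable for the planted effect sizes
exercised. A gene is declared differentially expressed at the dual
threshold p < 0.05 **and** FDR < 0.05. Per-stage expression summaries
are geometric means of the three replicate signals (equivalently,
arithmetic means of log2 signals); up/down counts between successive
stages use the sign of the change in those summaries.

## Temporal profiles (STC)

The Series Test of Cluster enumerates model profiles independent of
the data: with T = 5 stages and unit steps (`c = 1`, i.e. each
inter-stage transition is −1/0/+1), all `3^4 = 81` cumulative-sum
shapes are kept. The published analysis reports profile numbers up to
76, consistent with a full 81-profile catalogue, so no representative
subsetting is applied at this size (greedy max–min selection under
`1 - r` is available for larger T). A profile's id is the
base-3 encoding of its shifted transitions, most significant digit
first; ids are internally stable but are not expected to match any
external numbering.

Each gene's per-stage log2 series, referenced to 0 HAI, is assigned to
the non-flat profile with the highest Pearson correlation (ties break
to the lowest id; the flat profile is excluded because correlation
with a constant sequence is undefined, and zero-variance genes are
excluded and reported). Significance: for every one of the 120
orderings of the five stages — enumerated exhaustively, identity
included — all genes are re-assigned; a profile's expected count `E_p`
is the mean over orderings and its p-value is the upper binomial tail
`P(X >= n_p)` with `X ~ Binomial(N, E_p/N)`, the standard convention
for this test. Profiles with p < 0.05 are significant (no multiplicity
correction by default, matching the published criterion; a Bonferroni
flag would be a one-line change on the returned table). Significant
profiles are grouped by single-linkage connected components at
sequence correlation ≥ 0.7.

Fold changes between stages are ratios of the geometric-mean signals,
reported with their nearest-integer fold. The shipped
`germination_markers()` table reproduces the worked examples: the
PPFK transcript CD866884 rises 6.95-fold (≈7) from 0 to 12 HAI and
the two PK transcripts BJ252827/CK207050 rise 14.2- and 15.2-fold
(≈14 and 15).

## Clustering and category aggregation

Hierarchical clustering uses correlation distance `1 - r` with average
linkage — the common Cluster 3.0 configuration; `hca()` delegates the
agglomeration to `stats::hclust` and is verified against an O(n³)
textbook oracle in the test suite. Functional-category (BIN-style)
aggregation averages member genes' `log2(signal_t / signal_0)` ratios
per category; categories with fewer than 3 measured members are
dropped from reports so single-gene "categories" cannot dominate a
heatmap.

## Enrichment and path-net

Pathway enrichment tests each term's 2×2 table with the two-sided
Fisher exact test — the "probability mass no larger than observed"
rule, stated explicitly because two-sided Fisher has competing
definitions — plus a chi-square test without continuity correction,
flagged unreliable whenever an expected count is below 5. FDR across
terms is Benjamini–Hochberg (the usual reading of "FDR-corrected");
significance again uses the dual p < 0.05 and FDR < 0.05 threshold.
The universe defaults to all measured genes; restricting it to genes
with at least one Present detection call is a caller-side choice. The
path-net is the induced subgraph of curated pathway-to-pathway
relations on the significant terms, ranked by indegree + outdegree.

## Gene networks

The signal-net induces the typed interaction table (activation,
phosphorylation, and the undirected codes `b` = binding/association
and `c` = compound) on the DE genes after translating them through a
1→1 ortholog map; unmapped genes are dropped and reported. Self-loops
are removed and duplicate edges collapse with weight summation. Node
degree is the sum of incident connection strengths
`K_i = Σ_{u≠i} a_ui` (weights default to 1); indegree/outdegree count
directed edges only.

Co-expression edges connect gene pairs with `|r| ≥ 0.8` (Pearson,
computed across all 15 arrays rather than the 5 stage means — more
degrees of freedom for the correlation t-test; a means-level run is a
matter of passing the summarized matrix) whose BH-corrected
correlation-test p-value is below 0.05; the published workflow does
not state its cutoff, so these defaults are exposed as arguments. Edge
signs record positive versus negative co-expression. The k-core
decomposition runs classic peeling on the simple undirected graph;
core numbers are nested by construction and the implementation is
cross-checked against brute-force peeling (and `igraph::coreness`
where available). Core genes are ranked by (core number, simple
degree, id).

## Synthetic data: what it emulates and what it does not

`sim_config()` / `generate_expression()` generate the 5×3 design with
log-normal baselines (log2 mean 8, sd 2 — a plausible microarray
signal scale), additive Gaussian log2 noise (default sd 0.2, in line
with well-replicated arrays; the published experiment reports
replicate correlations above 0.98), planted profile genes
(`amplitude` × cumulative profile, default 1 log2 unit per step),
planted co-expression modules driven by a shared per-sample latent
factor with ±1 loadings, and flat genes. `generate_probe_level()` adds
per-probe log-normal affinities reused across arrays — the
probe-specific confounding that summarization must absorb — plus
optical background, a 5% cross-hybridization fraction on MM, and
additive intensity noise. `generate_annotations()` plants enriched
pathways by odds-ratio-weighted sampling of profile genes, emits
module cliques as typed edges, and a one-to-one ortholog map.

The generator does **not** emulate CEL-level spatial artifacts,
dye/batch effects, probe saturation, or the heavy-tailed noise of real
hybridizations, so passing tests demonstrate the pipeline's
correctness and calibration under its stated model, not robustness to
those artifacts. The published dataset-level totals (tens of
thousands of probe sets, thousands of DE transcripts) depend on the
real arrays and are deliberately out of scope at desk scale.

## Problem sizes and numerical choices

The test suite and the acceptance script run at sizes chosen to make
the statistical claims sharp while keeping a full run in the order of
seconds per stage: 2,000 genes for null calibration, 300 planted DE
genes at amplitude 2 and noise 0.2 over 10 seeds at 200 permutations
for FDR operating characteristics, 500 genes on 4 planted profiles
for STC recovery, and 500 random 2×2 tables / 100 random graphs for
the oracle-equivalence suites. All randomness flows from explicit
integer seeds; a fixed seed reproduces every stage byte for byte.

Degenerate inputs are handled explicitly rather than silently:
fewer than 50 features refuse background estimation (the lowest 2%
is ill-defined), fewer than 3 probe pairs refuse a detection call,
all-equal variances refuse the RVM fit, `c = 0` refuses profile
enumeration (only the flat profile would remain), zero-variance genes
are excluded and reported by both the STC assignment and the
co-expression stage, and every pipeline stage failure aborts with the
stage's name.

## Interfaces

Interchange is plain text throughout: tab-delimited expression
matrices and design tables, GMT gene sets, and SIF-like typed edge
tables (`A b B`, with an optional weight column). `run_pipeline()`
wires the stages together — simulate (or read), test, cluster, enrich,
build networks — writes per-stage TSV tables with a provenance header,
a YAML summary of headline counts, and is driven by a single
`default_run_config()` object that round-trips through YAML. R
functions plus that configuration object are the package's interface;
`inst/scripts/run_pipeline.R` wraps it for shell use.
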