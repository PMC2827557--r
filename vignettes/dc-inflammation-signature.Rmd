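---
title: "Deriving and validating a dendritic-cell inflammation signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating a dendritic-cell inflammation signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Dendritic cells (DCs) switch between a steady state and an activated,
inflammatory state in response to microbial products and inflammatory
stimuli, while glucocorticoids and related signals push them the other way.
`dcsignature` implements a complete pipeline for deriving a compact
transcriptional signature that classifies DC samples as *inflammatory* or
*non-inflammatory* from a two-class expression compendium, and for
validating that signature against independent qRT-PCR panels with a
direction-aware threshold-scoring statistic. Because the compendium the
design emulates (115 arrays over 12 stimulus groups) is not publicly
deposited, the package ships a first-class synthetic generator that
reproduces the design's statistical structure with known ground truth, so
every stage can be tested by parameter recovery.

```{r, eval = FALSE}
library(dcsignature)
report <- run_pipeline(dc_config(seed = 1))
print(report)
```

## Data model

* **Expression matrix** — probe sets × samples of log2-scale normalized
  expression-index values (the pipeline starts downstream of probe-level
  summarization; computing expression indices from raw arrays is out of
  scope). Probe-set identifiers follow the `<n>_at` convention of the
  MG-U74Av2 array.
* **Sample sheet** — per-sample stimulus, time point (hours), replicate and
  the binary class. Time points are treated as replicate samples of their
  stimulus; the classifier does not model the time course.
* **QC metrics** — per-sample 3′/5′ signal ratios for the β-actin and GAPDH
  probe sets. Ratios above 3.0 indicate degraded targets; `qc_filter()`
  excludes such samples with a strict `> 3.0` rule (a ratio of exactly 3.0
  is retained).
* **Ct table** — qRT-PCR threshold cycles for target genes and the 18s
  housekeeping gene, per gene × condition × replicate, with an untreated
  reference condition.

## The classifier

### Bagged classification trees

`dc_forest()` grows `n_trees` (default 1000) classification trees, one
independent bootstrap sample per tree (sampling with replacement, size equal
to the training-set size), with `mtry` (default `floor(sqrt(p))`) candidate
genes per split, split quality measured by the decrease in Gini impurity

$$G(t) = 1 - \sum_{c} p_c(t)^2,$$

and growth to purity (minimum node size 1). Tree growing is delegated to
the \pkg{randomForest} engine; bootstrap membership and the fitted trees
are retained, and out-of-bag (OOB) error and Gini importance are recomputed
from them from first principles, which keeps both quantities exactly
reproducible and independently testable. A sample's OOB prediction is the
majority vote of the trees whose bootstrap excluded it; test samples are
classified by majority vote over all trees. Exactly even votes resolve to
`non_inflammatory` — conservative toward the steady state, and exposed in
one place so the convention is testable.

### Gini importance

For gene $j$, the importance is

$$I_j = \frac{1}{T}\sum_{t=1}^{T} \sum_{d \in \text{splits}(t, j)}
  \frac{n_d}{n}\Big(G(d) - \tfrac{n_L}{n_d} G(d_L) - \tfrac{n_R}{n_d} G(d_R)\Big),$$

i.e. the impurity decrease weighted by the node's share of the tree's
bootstrap sample, averaged over trees. Because the decreases telescope, a
single tree grown to purity has $\sum_j I_j$ equal to its root impurity —
an identity the test suite checks exactly. This fraction-normalized
statistic equals the engine's raw "mean decrease in Gini" divided by the
training-set size; the equality (to machine precision) is used as an
independent cross-check in the tests.

### Backward elimination

`dc_signature()` repeats: train a forest on the current gene set, record
the OOB error, drop the least-important `drop_fraction` (default 0.2) of
genes, until two genes remain. The signature is the smallest set along the
trajectory whose OOB error is within `se_rule` (default 1.0) binomial
standard errors of the minimum observed OOB error,
$\mathrm{se} = \sqrt{e_{\min}(1-e_{\min})/n}$ — the published default of
the backward-elimination variable-selection method for expression
forests. Both parameters are exposed. Per-round forests use sub-seeds
derived deterministically from the master seed, so the whole path replays
exactly.

Two properties of this rule are worth stating plainly, because they shape
what the pipeline returns:

* **Parsimony.** When a few strong genes already classify the training set
  perfectly, $e_{\min}=0$, its standard error is 0, and the rule returns a
  *minimal* perfectly-discriminating subset. In recovery simulations with
  20 planted genes of standardized effect 2 in 30 + 30 samples, the
  selected sets are essentially free of noise genes (contamination ~0) but
  typically contain only a fraction of the planted set (~4–10 genes): the
  redundant planted genes are interchangeable, and the rule deliberately
  keeps few of them. A signature of fixed, larger size — for instance to
  mirror a historical 54-gene panel — is available through `top_k`, which
  ranks by full-model importance.
* **Selection bias.** The chosen round's OOB error is the (near-)minimum
  of many correlated estimates and is therefore biased low; on pure-noise
  data it lands well below the 50% chance level. It should be read as a
  selection criterion, not as an unbiased error estimate; unbiased
  assessment comes from the held-out test set.

### Directions

Each selected gene is annotated `up` if its mean expression among
inflammatory training samples exceeds its mean among non-inflammatory
ones, else `down`; the margin is recorded, and an exact tie is reported as
`up` with zero margin and a warning.

## Partitioning

`stratified_split()` assigns two thirds of the samples to training
(default), stratified by class, rounding half-up within strata and
reconciling against the rounded global target via the largest strata. With
the 115-sample design this yields 77 training and 38 testing samples
(53 + 24 by class). The historical realized training split of 50
inflammatory + 27 non-inflammatory is *not* the proportional outcome; it is
reproducible exactly through
`override_counts = c(inflammatory = 50, non_inflammatory = 27)`. Sampling
is keyed on sorted sample identifiers, making the assignment invariant to
file row order.

## The qRT-PCR scoring statistic

Relative expression is quantified by the $2^{-\Delta\Delta C_t}$ method:
$\Delta C_t = C_t^{\text{target}} - C_t^{18s}$ per replicate,
$\Delta\Delta C_t$ subtracts the gene's untreated-reference $\Delta C_t$
(averaged over reference replicates), and each gene × condition cell is the
arithmetic mean of its replicate fold changes (panels report mean fold
changes over independent experiments; replicate-level scoring is available
by passing single-replicate tables). The reference column is 1 by
definition.

For each gene, `derive_thresholds()` takes the median fold change over the
known inflammatory reference conditions and over the known
non-inflammatory ones; the threshold is the arithmetic mean of the two
medians — the one reading of "the mean expression level between the two
classes" that produces a single per-gene cutoff lying between the classes.
The untreated reference condition is excluded from threshold derivation
and scoring.

`score_condition()` awards a gene 1 point when its fold change falls on
the side of its threshold consistent with the claimed class: above for an
up-regulated gene under an inflammatory claim, below under a
non-inflammatory claim, and the reverse for down-regulated genes. All
other cases — including a value exactly at the threshold, since the
inequalities are strict — score 0. `concordance()` reports the fraction of
genes scoring 1 and its percent rounded half-up (half-up is the convention
consistent with printed pairs such as 51/54 → 94% and 43/54 → 80%).
`call_class()` turns the same per-gene comparisons into votes and calls
the majority, ties to `non_inflammatory`; whenever concordance under a
claim exceeds 1/2 the call equals that claim, a consistency the tests
verify by enumeration.

## The synthetic generator

`simulate_expression()` emulates the compendium the analysis assumes:

* 12 stimulus groups totalling 115 samples, 79 inflammatory and 36
  non-inflammatory, with the per-group time-point/replicate layout of the
  study design (e.g. 2/4/8/12/24 h in duplicate for the 10-array groups,
  triplicate for the 15-array group). One group enumeration in the source
  material (20 Listeria arrays) is inconsistent with these totals; the
  generator follows the consistent enumeration (10).
* Per-gene baseline means drawn once from a uniform range on log2 scale
  (4–12), mimicking expression-index ranges, plus Gaussian noise of sd
  `noise_sd` (default 0.5 log2 units) — the standard microarray error
  model, sufficient for recovery testing.
* A planted signature (default 36 up + 18 down) shifted by
  ±`effect_size`·`noise_sd` in inflammatory samples, so `effect_size` is
  the per-gene standardized separation (default 2, a strong but realistic
  single-gene effect for activation markers).
* QC ratios drawn so an expected `qc_fail_fraction` of samples exceeds
  the 3.0 threshold (default 0: the emulated dataset is post-QC).

`simulate_ct_table()` emits Ct values whose implied fold changes are
centred at $2^{\pm \mathrm{log2\_fc}}$ for direction-consistent
gene/condition pairs (default log2 fold 3). The 18s Ct is held constant —
the normalizer's noise is not separately identifiable within
$2^{-\Delta\Delta C_t}$ — and replicate noise is placed on the target Ct,
so zero noise makes the planted fold changes exactly recoverable, the
round-trip identity the tests exploit.

What the generator deliberately does **not** emulate: time-course
autocorrelation within stimulus groups (time points enter as replicates,
as the classifier treats them), gene–gene correlation, batch or lab
effects, heavy-tailed intensity noise, and probe-level artifacts. Passing
recovery tests therefore demonstrates correctness of the algorithms under
the stated error model, not robustness of the biology to structured noise
in real arrays.

## Numerical conventions and degenerate inputs

* Standard deviations use the $n-1$ denominator throughout.
* Constant gene rows cannot be z-scored; they are set to zero with a
  warning rather than dropped, keeping row indices aligned with
  annotation.
* PCA centres genes (no rescaling beyond what the caller applied — the
  canonical path z-scores first) and fixes each component's sign so its
  largest-magnitude loading is positive.
* Hierarchical clustering uses Euclidean distance with complete linkage by
  default; linkage is a documented option since only the distance is
  dictated by the method.
* Importance ties during elimination break lexicographically by gene id;
  vote ties resolve to `non_inflammatory`; percent rounding is half-up.
* Per-stage and per-round seeds derive from the master seed by a fixed
  affine map kept below $2^{31}$, recorded in the run report.

## Problem sizes used by the test suite

The packaged tests exercise the pipeline at reduced scale chosen to keep
the statistical claims sharp while remaining quick to run: simulated
matrices of 150–600 genes for pipeline and multivariate checks, recovery
experiments with 500 genes × 60 samples × 500 trees over 5 seeds, and
forests of 25–500 trees elsewhere. These sizes are the package's testing
choices; the defaults of the exported functions remain the full-scale
study conditions (1000 trees, 2/3 split, 115-sample design).

## Known limitations

* The OOB-guided selection is parsimonious by design (see above); it
  recovers a minimal discriminating subset, not every differentially
  expressed gene. Use `top_k` when a fixed-size panel is required.
* Thresholds derived from condition-level mean fold changes inherit the
  replicate structure of the panel; with very few reference conditions per
  class the medians are coarse.
* No amplification-efficiency correction is applied to Ct values beyond
  the validated-primer assumption.
* The pipeline starts from expression indices; probe-level summarization,
  annotation enrichment, and figure-perfect heat-map rendering are out of
  scope.
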