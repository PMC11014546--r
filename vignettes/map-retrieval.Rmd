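---
title: "Retrieval-based profile evaluation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrieval-based profile evaluation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapeval)
```

## The retrieval model

`mapeval` evaluates groups of high-dimensional profiles by asking how well
each group member *retrieves* the rest of its group from a ranked candidate
list. For one query profile with $M-1$ other group members (positives) and
$N$ admitted reference profiles, candidates are ranked by increasing
dissimilarity to the query and the ranking is reduced to a binary list
$g_1, \dots, g_{M-1+N}$. Average precision is

$$\mathrm{AP} = \sum_k (R_k - R_{k-1})\, P_k, \qquad
  P_k = \mathrm{TP}_k / k, \quad R_k = \mathrm{TP}_k / (M-1), \quad R_0 = 0,$$

equivalently the mean of $P_k$ over the ranks holding positives. The group
score is the mean over its $M$ queries (mAP). AP is rank-based, so any
strictly monotone transform of the dissimilarity leaves every score and
p-value unchanged; the method makes no distributional, linearity, or sample
size assumptions beyond exchangeability under the null.

The single modelling choice that matters is the dissimilarity. Cosine
distance ($1 - $ cosine similarity) is the default: profiling features are
typically standardized so that direction, not magnitude, carries the
phenotype, and cosine distance is invariant to per-profile rescaling.
Euclidean and Pearson-correlation distances are available for comparison;
in our simulations they behave similarly but separate shifted profiles
somewhat less efficiently.

Three assessments share this core, differing only in how queries, positives
and references are chosen from metadata:

* **activity** — positives are a perturbation's replicates, references are
  negative controls;
* **consistency** — profiles are per-perturbation consensus medians;
  positives share an annotation label, references carry other labels;
* **distinctiveness** — positives are a perturbation's replicates,
  references are all other perturbations' replicates.

A declarative block design (`grouping_spec()`) generalizes this: metadata
columns that must match (`pos_same`, `ref_same`) or differ (`pos_diff`,
`ref_diff`) between a query and its positives/references. Designs such as
"same well position, different plate" isolate plate effects from biological
signal. Filters are conjunctions of column-membership conditions; arbitrary
predicates are deliberately out of scope to keep designs serializable and
auditable. Queries with no admissible positive or reference are skipped and
logged with a reason code rather than aborting a screen-scale run.

For multiply-annotated perturbations, `multilabel_map()` scores one label at
a time: positives are the label's other members and references are all
perturbations *not* carrying that label (sharing a different label does not
exempt a profile from serving as a reference). The resulting sparse AP
matrix is aggregated over *present* entries only; treating absent
(perturbation, label) pairs as zeros would bias per-perturbation means
toward unannotated labels.

## Significance

Under the null hypothesis that positives and negatives are exchangeable in
the ranking, every placement of the $M-1$ positives among the $M-1+N$ ranks
is equally likely, so the AP null depends only on the pair
$(M-1,\, M-1+N)$ and has exactly $\binom{M-1+N}{M-1}$ configurations.
`null_ap()` enumerates this distribution when the count is at most $10^4$
(the default cap; enumeration at the cap takes well under a second and
covers every list shape that occurs in typical screens) and otherwise draws
uniformly random binary lists.

The group-level null is constructed by drawing, per permutation, one AP per
query from its list-shape null and averaging — the natural Monte-Carlo
analogue of reshuffling each query's rank list. P-values use add-one
smoothing, $p = (1 + b)/(1 + n_\mathrm{perm})$, so the smallest attainable
value is $1/(n_\mathrm{perm}+1)$ and q-value artifacts at zero are avoided;
with a single query and an enumerable null the exact tail probability is
returned instead. The default $n_\mathrm{perm} = 10{,}000$ resolves
p-values to $10^{-4}$, comfortably below the usual 0.05 threshold after
Benjamini–Hochberg correction across groups. Null distributions and
null-mAP samples are cached by list shape: a screen reuses the same handful
of shapes thousands of times, and sharing the seeded null sample across
same-shape groups preserves marginal validity while making the significance
pass essentially free.

One property of this construction deserves emphasis. The per-query APs of a
group are positively correlated — queries share replicates and references,
so a reference that happens to sit near the group's centroid hurts every
query at once — while the null treats them as independent. The null mAP
distribution is therefore slightly too narrow, and group-level p-values are
mildly anticonservative: in the package's own pure-null calibration check
(i.i.d. profiles, 500 groups of 4 replicates vs 12 controls) the raw
p < 0.05 rate for mAP runs above the nominal 5%, where the two permutation
baselines sit on it. Per-query AP p-values, and group p-values whenever
rank lists are genuinely independent, are exactly calibrated (the test
suite verifies both). Users comparing methods at a fixed nominal level
should keep this in mind; ranking perturbations by mAP or by p-value is
unaffected.

## Normalization and consensus

Two per-feature normalizations are provided, optionally within groups of a
metadata column (typically the plate): `standardize` (subtract the mean,
divide by the sample standard deviation) and `mad_robustize` (subtract the
median, divide by $1.4826 \times \mathrm{MAD} + \varepsilon$). The 1.4826
consistency constant makes the scaled MAD estimate the standard deviation
under normality; $\varepsilon$ (default $10^{-6}$) guards near-zero scales.
Features with exactly zero scale map to 0 — a constant feature carries no
ranking information either way. The sample (rather than population)
standard deviation is used, matching R's `scale()`; within equal-sized
groups the two differ by one global factor and produce identical rank
lists. Feature selection, sphering and batch correction are upstream
concerns and are deliberately not reimplemented here.

Consensus profiles are per-feature medians over a perturbation's
replicates; metadata columns that are not constant within every group are
dropped because they no longer describe the aggregated row.

## The simulation generator

`simulation_config()` / `simulate_condition()` emulate the simplest
controlled screening situation: control profiles with $d$ i.i.d. standard
normal features, and perturbation replicates in which a fraction $f$ of
features is shifted to mean 1 (SD 1), the remainder staying null. The
benchmark grid defaults — $d \in \{100, 200, 500, 1000, 2500, 5000\}$,
$f \in \{1, 2, 4, 8, 16, 32, 64\}\%$ on a binary exponential scale, 2–4
replicates against 12/24/36 controls, 100 perturbations per cell — span the
regimes from undetectable to saturated. A heavy-tailed variant draws from a
location-shifted Cauchy, and `shift`/`scale` are configurable. The shifted
features are the first $\mathrm{round}(f \cdot d)$ columns: features are
i.i.d., so the index choice is immaterial, and determinism aids debugging.
Fresh controls are drawn per perturbation instance by default (independent
null); `share_controls = TRUE` reuses one control set per condition for
screen-realistic dependence.

What the generator does *not* emulate bounds what passing benchmarks show:
real profiles have correlated features, plate and batch structure,
heteroscedastic noise and outliers. The simulations establish relative
power and type-I behaviour of the four methods under clean conditions, not
absolute performance on any real assay; the block-design machinery exists
precisely because real data violate these simplifications.

`run_benchmark()` applies the chosen methods to the same generated data per
cell and reports recall: the fraction of the cell's perturbations with raw
p below 0.05 (a flag switches to BH-corrected p-values; k-means contributes
its separation indicator instead of a p-value). Raw p-values are the
default because each cell's 100 perturbations are interchangeable
replicates of one condition, not a family of competing hypotheses.

## Baseline methods

* **mp-value** — principal components of the pooled sample, scores weighted
  by explained-variance fraction, Mahalanobis distance between group
  centroids under the pooled within-group covariance of the weighted
  scores, ridge-regularized with $\lambda = 10^{-6} \cdot
  \mathrm{tr}(\Sigma)/d$ for rank deficiency at $n \ll d$. Because the PCA
  is fit on the pooled sample it is independent of the group labels, so
  refitting it per permutation would be a no-op; labels enter only the
  centroid/covariance step and the PCA is fit once.
* **MMD** — unbiased estimator of squared maximum mean discrepancy with RBF
  kernel $\exp(-\lVert x-y\rVert^2 / 2\sigma^2)$, $\sigma$ set to the
  median pairwise Euclidean distance of the pooled sample. For equal group
  sizes the paired U-statistic form is used (cross terms $i \ne j$ only),
  so identical point sets give exactly zero; for unequal sizes the general
  unbiased form applies. The kernel matrix is computed once and permuted by
  index; the bandwidth is label-free.
* **k-means** — $k = 2$, ten random restarts, lowest within-cluster sum of
  squares kept; the groups count as separated only when the clustering
  reproduces the group partition exactly (up to label swap).

Both permutation baselines use add-one smoothed p-values, and permutation
draws that recreate the observed partition are rejected — the observed
labeling is exactly the event the add-one term accounts for, and
double-counting it keeps perfectly separated groups from reaching the
resolution bound $1/(n_\mathrm{perm}+1)$. The baseline default
$n_\mathrm{perm} = 1{,}000$ reflects their per-call cost across a
simulation grid; the mAP path shares nulls across a cell and affords
$10{,}000$.

## Numerical choices and degenerate inputs

* Ties in rank lists are broken by original row index (stable sort). Ties
  have probability zero for continuous features; the rule exists so that
  pathological inputs remain deterministic.
* Observed-vs-null comparisons use a $10^{-12}$ slack on the $\ge$ so that
  equal floating-point APs count as ties rather than falling either side
  of the threshold.
* Cosine distance is undefined for all-zero profiles and correlation
  distance for constant profiles; both raise errors that identify the
  offending query or group rather than propagating NaNs.
* Exact-null supports are matched on exact floating-point values when
  collapsing enumerated configurations; distinct APs that differ only in
  the last bits remain distinct support points, which is harmless for tail
  probabilities.
* Monte-Carlo reproducibility: every sampling routine takes a seed and
  restores the caller's RNG state; the benchmark derives one child seed per
  grid cell, so adding cells or methods never changes other cells' draws.

## Test problem sizes

The test suite verifies the enumerated AP null against exhaustive
mean-precision oracles for all binary lists up to length 12, compares
Monte-Carlo against enumerated nulls at $10^5$ draws across eight
representative list shapes spanning support sizes 3 to 9,880 (a
Kolmogorov–Smirnov distance below 0.01; the family of shapes with
enumerable nulls is unbounded, so a representative spread substitutes for
"all"), calibrates the permutation machinery on 500 null groups, and runs
the benchmark's hard (1% perturbed), saturated (64% of 5,000 features) and
monotonicity regimes at 100 perturbations per cell with 10,000
permutations. These sizes keep the full suite under a few minutes while
leaving the binomial error of every rate assertion well inside its asserted
tolerance.

## Known limitations

* Group-level mAP p-values are mildly anticonservative, as analyzed above.
* Relevance is binary; graded similarity (partial matches) is not modelled.
* AP saturates at 1: beyond perfect separation the score cannot reflect
  effect size.
* Permutation resolution limits significance for very small $M$, $N$; with
  2 replicates against 12 controls the exact AP null has only
  $\binom{13}{1} = 13$ configurations, and no perturbation can reach a very
  small per-query p-value regardless of effect size.
* The constraint language covers equality/inequality block designs;
  continuous covariates (dose, time) must be discretized by the user.
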