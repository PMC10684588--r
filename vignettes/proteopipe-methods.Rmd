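---
title: "Methods: matched-cohort proteomic analysis with proteopipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched-cohort proteomic analysis with proteopipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteopipe)
```

proteopipe implements the downstream statistical analysis of a label-free
DIA proteomic cohort of matched primary tumors and distant metastases,
starting from a quantified protein-by-sample intensity matrix. This
vignette describes the statistical model of each stage, the tunable
parameters and their defaults, the synthetic-data generator used to
validate the pipeline, and the design decisions taken where the analysis
recipe left genuine freedom.

## The analysis problem

Each of `n` patients contributes one primary lung-adenocarcinoma sample
and one or more distant metastases, all FFPE, profiled by DIA mass
spectrometry. The input is a protein-by-sample table of positive
intensities with substantial missingness — FFPE proteomes are degraded,
and faint signals drop out preferentially (missing not at random, MNAR).
The pipeline answers three questions:

1. Which proteins differ between pooled primaries and pooled metastases?
   (Mann–Whitney differential expression with a volcano classification.)
2. What sample structure exists beyond the primary/metastasis contrast?
   (Consensus NMF clustering with data-driven rank selection, plus PCA.)
3. Which proteins drive both? (Intersection of the differential set with
   the cluster-relevance set, the candidate nomination step.)

## Stage by stage

### Valid-value filter

Proteins quantified in fewer than `min_valid_fraction` (default 0.5) of
all samples are removed. The comparison is inclusive (a protein seen in
exactly half the samples is kept) and counts all samples, not per-group
counts. The filter is idempotent and monotone in the threshold.

### Invariant-protein median normalization

Per-sample depth offsets (loading, digestion efficiency, instrument
drift) are removed by anchoring every sample to a panel of invariant
proteins. Among proteins quantified in *every* sample, the
`n_invariant = 100` with the smallest cross-sample variance of log2
intensity are selected (ties broken by protein id; if fewer complete
proteins exist, all are used with a warning). The offset of sample *j*
is the median of its invariant-protein log2 values minus the grand
median of those per-sample medians; subtracting it equalizes the
invariant-protein median across samples. Offsets act on the log2 scale,
i.e. divisively on raw intensities. The procedure is idempotent and, on
simulated data with planted offsets and genuinely constant invariant
proteins, recovers them exactly up to a common constant.

The invariance criterion itself is pluggable (`statistic` argument of
`select_invariant()`): low variance is the default because it is the
simplest defensible notion of "invariant"; more elaborate
variance-vs-intensity modelling can be slotted in without touching the
rest of the pipeline.

### Differential expression

Each protein is tested between all primaries and all metastases with an
unpaired two-sided Mann–Whitney U test over its valid, *unimputed*
values. An unpaired test is deliberate: patients contribute unequal
numbers of metastases, and a paired design would weight patients
unevenly. The U statistic counts pairs with the primary value larger
(ties count one half). P-values are exact by enumeration when the
combined sample size is at most 12 and there are no ties; otherwise the
normal approximation with tie correction and continuity correction is
used. At the cohort's group sizes (14 vs 24) the asymptotic branch
applies.

The log2 fold change is the difference of per-group means of log2
intensities, primary minus metastasis — negative values mean higher in
metastases. A median-based estimator is available by argument. The
volcano classification uses the *unadjusted* p-value (default threshold
0.05) together with an absolute log2-fold-change threshold (default
0.5); Benjamini–Hochberg adjusted p-values are always reported
alongside. The unadjusted headline call is intentional: the cluster
analysis provides an orthogonal line of evidence, and the intersection
step (below) is the guard against false positives. Proteins with fewer
than two valid values in either group are reported untested (`p = NA`)
and never enter significance counts.

### Consensus NMF and rank selection

Unsupervised structure is sought by non-negative matrix factorization of
the mean-imputed log2 matrix. Missing values are replaced by the
*per-protein* mean of valid values — a conservative choice that shrinks
group differences rather than inventing them ("mean of all valid
values" read as the protein-level mean; the global-matrix-mean variant
is available as `impute_mean(method = "global_mean")` for sensitivity
analysis). Imputation feeds *only* PCA and NMF; the tests above and the
enrichment below always use unimputed data, which the pipeline enforces
by wiring rather than convention. If the log2 matrix contains negative
entries it is shifted globally so its minimum is zero; the shift is
recorded in the run manifest.

`nmf_fit()` minimizes the squared Frobenius reconstruction error with
Lee–Seung multiplicative updates, whose per-iteration error sequence is
provably non-increasing — a property the test suite asserts directly.
Initialization is stochastic "random vcol": each basis column starts as
the average of five random data columns. On log-scale intensity data,
which has a dominant flat component, this converges an order of
magnitude faster than uniform-random initialization and reaches
markedly better optima within the iteration budget (default
`max_iter = 3000`, relative tolerance `1e-9`; the budget matters — with
loose settings the restarts do not converge far enough for their
cluster assignments to stabilize, and the consensus machinery below
degrades).

For each rank `k` in the sweep (default 2–10), `n_runs = 50` restarts
are run from different seeds. Each run assigns every sample to its
largest coefficient in `H`; the consensus matrix averages the
co-assignment indicator over runs. Two diagnostics summarize its
crispness: the **cophenetic correlation** between consensus distances
`1 - C` and the cophenetic distances of their average-linkage
dendrogram, and the **dispersion coefficient**
`mean(4 (C - 1/2)^2)`, which is 1 for a perfectly reproducible 0/1
consensus and 0 for a maximally ambiguous all-½ one. `select_rank()`
operationalizes the "distinctive peak for both" rule deterministically:
the smallest interior rank that is a *strict* local maximum of both
sequences; if none exists, the rank with the global cophenetic maximum,
with a warning. Final sample labels cut the average-linkage tree of
`1 - C` at the selected rank — consensus-based labels are robust to the
component-relabelling that plagues single runs.

### Kim–Park relevance scores

How specifically a protein loads on one cluster is scored from the
basis matrix `W` of the lowest-error restart at the selected rank: the
row is normalized to a probability profile and the score is one minus
its normalized entropy. One-hot rows score 1, uniform rows 0, and the
score is invariant to row rescaling. Proteins strictly above the 90th
linear-interpolation percentile (~10% of proteins) form the
cluster-relevant set.

### Phenotype-permutation GSEA

Gene sets in GMT format are tested on the primary-vs-metastasis
contrast. Proteins are ranked by a pooled-variance two-sample t
statistic (variance floored at `1e-8` so ties cannot produce infinite
statistics); the enrichment score is the classic weighted
Kolmogorov–Smirnov running sum (hit increments proportional to
`|t|^weight`, default weight 1). The null distribution permutes the
*tissue labels* (default `n_perm = 100`, seed 7) and re-ranks, which
preserves the correlation structure among proteins — the appropriate
null when whole samples, not genes, are exchangeable. Nominal p-values
use the `(1 + b)/(1 + m)` convention over same-sign permutation scores,
so they can never be zero at finite `n_perm`; NES divides the ES by the
mean same-sign permutation magnitude, and FDR q-values pool the
sign-matched permutation NES distribution in the standard way. Set
sizes are bounded to [5, 500] after intersection with measured
proteins. Protein ids are matched to set members directly unless a
two-column mapping is supplied.

### Candidate nomination and immunoblot statistics

Candidates are proteins present in both the significant DE set
(unadjusted `p <= 0.05`; optionally restricted to the
fold-change-qualified classes) and the cluster-relevant set — two
orthogonal criteria. For validation experiments, `blot_normalize()`
makes densitometric band intensities comparable across gels by dividing
each sample by the mean of the same-gel cross-blot standards and then
by its loading control; `blot_compare()` applies the same Mann–Whitney
test as the proteomic stage.

## The synthetic cohort generator

Because raw cohort data cannot ship with the package, every stage is
validated on synthetic cohorts with known ground truth
(`simulate_cohort()`). The generator emulates the study regime:

* **Design**: 14 patients, one primary each, and per-patient metastasis
  counts drawn uniformly from 1–4 and nudged to a total of 24 — 38
  samples.
* **Abundances**: per-protein log2 baselines `N(20, 2)`, within-protein
  residual scatter `N(0, 0.8)`, per-sample depth offsets `N(0, 0.3)`;
  raw intensities are `2^x`. The residual scale 0.8 is a typical
  protein-level biological-plus-technical spread for label-free FFPE
  data and gives, at 14-vs-24 group sizes, realistic (high but not
  saturated) power for 1-log2-unit effects.
* **Planted signal**: `n_de_proteins = 100` proteins get a signed
  `de_effect` (default 1.0 log2 units) added to metastasis samples;
  a disjoint block of `n_cluster_proteins = 30` proteins encodes
  `n_clusters = 3` sample clusters separated by `cluster_effect = 2.0`.
  Keeping the blocks disjoint keeps the two truths separable in tests.
* **Missingness**: applied after effect planting so MNAR interacts with
  group differences. Each entry drops out with probability
  `mar_rate + (1 - mar_rate) * plogis(-mnar_slope (x - mnar_midpoint))`.
  The defaults (midpoint 18.65, slope 2.1, MAR floor 0.005) were
  calibrated once against the cohort's printed coverage — a median of
  ~1003 of 1405 proteins per sample, ~1055 proteins surviving the 50%
  filter, and ~334 complete proteins — and then frozen. The true
  MNAR/MAR mix of the real data is unknown; the generator reproduces
  the coverage arithmetic, not the mechanism, so passing tests certify
  the pipeline's behavior under a *plausible* FFPE regime, not under
  the real instrument's.

What the generator does not emulate: peptide-level structure,
chromatographic drift or batch blocks beyond per-sample offsets,
patient-driven covariance between matched samples, and heavy-tailed
intensity distributions. Conclusions about those features cannot be
drawn from the simulation tests.

## Numerical choices and degenerate inputs

* Exact-vs-asymptotic U-test switch at combined n = 12; exact refused
  under ties.
* `filter_valid` uses an inclusive `>=` ("at least 50%").
* Quantile for the relevance threshold: linear interpolation (type 7),
  strict `>` comparison.
* All-zero basis rows score 0 with a warning; consensus matrices with
  zero off-diagonal variance return `NA` cophenetic correlation with a
  warning; sweeps shorter than three ranks fall back to the global
  cophenetic maximum.
* PCA component signs are fixed by making the largest-magnitude loading
  positive, so results are fully deterministic.
* Stage seeds are derived from the root seed by fixed offsets (NMF uses
  `seed + 211`, each rank adds `1000k`, each restart increments by 1),
  so any stage can be reproduced in isolation; the same configuration
  and seed reproduce every numeric table byte for byte.

## Problem sizes used in the shipped checks

The package's own validation runs at desk scale: calibration of the
type-I level uses 50 null cohorts of 300 proteins; DE sensitivity uses
20 cohorts of 200 proteins at the cohort's 14-vs-24 group sizes;
GSEA null calibration uses 10 datasets of 80 proteins at 100
permutations; and cluster-structure recovery uses 20 cohorts of 120
proteins with a rank sweep over 2–5 at 30 restarts. The full-size
configuration (1405 proteins, ranks 2–10, 50 restarts) is the default
for real analyses.

## Known limitations

* The invariant-protein selector is a low-variance heuristic; cohorts
  where most complete proteins are genuinely regulated would bias the
  offsets.
* Mean imputation biases clustering toward the cohort average for
  heavily missing proteins; the NMF consumes it by design, but results
  for proteins near the 50% filter boundary should be read cautiously.
* The GSEA FDR uses the standard pooled-permutation estimator, which is
  conservative for strongly correlated sets at small `n_perm`.
* Consensus NMF inherits the usual caveat that the rank diagnostics can
  prefer a sub-split of a true cluster when genuine substructure exists.
  Two culprits recur on simulated cohorts: per-sample depth offsets
  (normalize first — unnormalized cohorts routinely mis-select the rank)
  and, under heavy dropout, the imputation itself — samples with low
  coverage share many per-protein mean values, resemble each other, and
  can form a stable, reproducible "coverage cluster" that both rank
  diagnostics legitimately prefer. On simulated three-cluster cohorts
  with the full FFPE dropout regime this raises the selected rank by
  one in roughly a fifth of cohorts, while the planted clusters remain
  intact within the finer partition; on complete data the planted rank
  is recovered essentially always. Inspecting per-sample coverage
  alongside the cluster labels is therefore part of reading the output.
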