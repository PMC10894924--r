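---
title: "stimnet: models, design choices and validation conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stimnet: models, design choices and validation conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stimnet` analyses how a clinical covariate modulates per-patient
transcriptional responses to an acute stimulus. This vignette is the
package's own account of the statistical models it implements, the design
decisions taken where the methodology was genuinely open, and what the
synthetic-cohort validation does and does not establish.

## The data model

The unit of analysis is the **response matrix**: for each gene `g` and
patient `p`, `log2FC(g, p)` is the difference of log2 expression between the
stimulated and baseline sample of that patient. All network stages operate on
this matrix, not on the raw intensities, because the scientific object is the
*response* and its inter-patient variation. The clinical table carries 14
risk factors — four binary (sex, renal failure, current smoking, diabetes)
and ten continuous (age, BMI, heart rate, DBP, SBP, glucose, triglyceride,
creatinine, HDL, LDL) — with DBP (mmHg) as the focal trait.

## Preprocessing

* **Detection.** A gene is detectable in a sample when its intensity exceeds
  the 95th percentile of the negative-control intensities; samples with
  fewer than `min_detected` (default 9000) detectable genes are dropped.
  Proprietary array software reports an equivalent detection p-value; the
  control-quantile exceedance is the same contract with transparent math.
* **Gene filters.** Genes below 7.5 log2 units in *every* sample are
  borderline and removed; then genes with response SD below 0.5. The SD is
  computed on the log2FC scale when pairing exists (the filters exist to
  stabilize the response-based networks, so the response scale is the
  relevant one; on unpaired data the intensity scale is used).
* **Outliers.** Patients are flagged when their mean Euclidean distance to
  all other patients exceeds the Tukey upper fence `Q3 + k·IQR` (k = 3).
  A `median + 3·MAD` fence was considered and rejected: at cohort sizes of a
  few dozen the MAD's own sampling error produces a null flag rate above
  10%, while the IQR fence measured 0.7% over 300 null cohorts with full
  power against a patient shifted by 3 log2 units on every gene. Flagging
  more than 20% of the cohort downgrades removal to a warning unless forced.

## Moderated differential response

Per gene the null is a zero mean log2FC. Residual variances are shrunk by
empirical Bayes: a scaled inverse-chi-square prior `(d0, s0²)` is fitted by
matching moments of the log-variances (the trigamma-inverse construction),
the posterior variance is the df-weighted blend, and the moderated t gains
`d0` degrees of freedom. When the spread of log-variances is no larger than
its sampling noise the prior df is infinite and all variances pool; with
`prior_df = 0` the ordinary one-sample t is recovered exactly. The test
suite cross-checks t-statistics, p-values and the fitted prior df against
`limma` on shared inputs, and verifies type-I calibration (0.05 ± 0.02) on
null cohorts of 2000 genes × 38 patients.

## Co-expression modules

Unsigned soft-threshold adjacency `|cor|^5` (power fixed at 5; the signed
transform `((1+cor)/2)^5` is available by flag), topological overlap
dissimilarity, and average-linkage hierarchical clustering. Three choices
deserve comment:

* **Cut semantics.** `cut_height` (default 0.995) applies to the *raw*
  dissimilarity scale, which is already in [0, 1]. Normalizing by the
  tallest merge was tried first and rejected: noise genes chain into the
  tree just below the maximum, so a normalized 0.995 cut absorbed roughly
  half the noise genes into modules (planted-module ARI ≈ 0.3).
* **Membership pruning (kME).** After the cut and the minimum-size rule
  (50 genes), genes whose correlation with their module eigengene falls
  below `min_kme = 0.5` are released to `unassigned`, iterating until
  stable. This is the standard module-membership notion in weighted
  co-expression practice; it is what makes the simplified static cut behave
  like a dynamic cut on clean signal: planted six-module cohorts
  (2000 genes × 38 patients, within-module correlation 0.7) are recovered
  with ARI ≈ 0.98, and pure-noise matrices leave every gene unassigned.
* **Merging.** Modules whose eigengene dissimilarity `1 − cor` is below 0.2
  merge iteratively; a second merge pass is a no-op (tested).

Eigengenes are first right singular vectors of the standardized module
submatrix, with sign fixed to correlate positively with the module's mean
profile so results are deterministic.

## Bayesian consensus network

Nodes are the modules plus the trait. Per iteration, 20 genes per module are
drawn (without replacement where possible), averaged per patient, and a DAG
is learned by greedy hill climbing (add/delete/reverse) on the
linear-Gaussian BIC, `logL − (params/2)·log n`, with deterministic
lexicographic tie-breaking. On 3-node problems the search attains the
exhaustive-search optimum over all 25 DAGs in ≥ 95% of random instances.

Only genes are resampled; the trait column enters every iteration unchanged.
Patient resampling is available (`resample_patients = TRUE`) but off by
default, following the literal bootstrap description of the procedure this
reimplements. Edge strength is the fraction of iterations containing the
edge in either direction; direction confidence the majority share given
presence. The retention threshold is the elbow (maximum distance to the
chord) of the empirical strength CDF — computed with never-observed node
pairs included at strength 0, so a lone strong edge is retained rather than
becoming its own degenerate chord. The elbow is a property of each run's
strength distribution, not a constant; a fixed override is available.
Residual cycles are resolved by admitting edges in decreasing strength and
skipping any that would close a cycle.

The planted module→DBP effect (correlation 0.6 at n = 38) is recovered with
strength ≥ 0.8 and retained in ≥ 80% of seeds at 200 iterations. The null
check runs at n = 200 patients: at n = 38 the BIC's effective correlation
threshold (|r| ≈ 0.30) is low enough that chance correlations between
independent module factors produce persistent spurious edges in any
gene-resampling scheme, which is a property of the cohort size, not of the
search; at n = 200 null cohorts yield at most one consensus edge in ≥ 90%
of seeds.

## Regulatory network and TF activity

**MI estimator.** Rank-binned plug-in MI with
`B = max(2, floor(sqrt(n/5)))` equal-frequency bins and Miller–Madow bias
correction, clipped at zero — symmetric, invariant under monotone
transforms, within ±0.15 nats of the Gaussian closed form
`−½·log(1−ρ²)` at ρ = 0.9, n = 5000.

**Thresholds.** The absolute MI floor (0.5 nats) is combined with the 95th
percentile of a permutation null, because absolute MI scales with the
estimator. At 38 patients the estimator has only 2 bins and its ceiling
(log 2 ≈ 0.69) sits close to the floor, so regulon-recovery validation runs
at 200 patients, where B = 6; this is a resolution property of histogram MI
at small n, stated here as the package's validation condition.

**DPI.** In every fully connected triangle the weakest edge is removed when
below `(1 − tolerance)` times the smaller of the other two, evaluated
simultaneously against the pre-pruning graph; tolerance 0 (strict) by
default, values ≥ 1 disable the filter. Equality with an all-triangles
oracle is tested exactly.

**Consensus.** Edge occurrences across bootstraps are compared with a
Poisson background whose rate is the total number of retained edge slots
divided by the number of *possible* TF–gene pairs, Bonferroni-corrected
across observed edges at `Padj < 0.05`. Dividing by observed edges instead
(an alternative reading of the source description) degenerates on clean
data: when every true edge recurs in all bootstraps the background equals
the maximal support and nothing is significant, contradicting the obvious
requirement that an edge present in all bootstraps be kept. Planted regulons
(15 TFs × 10 targets among 600 genes, 200 patients) are recovered with
precision and recall 1.0 and mode-of-regulation sign accuracy 1.0.

**TF activity.** Single-tail analytic rank enrichment: per patient the gene
responses become `qnorm((rank − 0.5)/n)` scores and
`NES = Σ mor_i w_i q_i / sqrt(Σ (mor_i w_i)²)`, exactly standard normal for
an exchangeable null draw of targets. The two-tail magnitude component and
pleiotropy correction of the full published method are deliberately
omitted; planted-activity recovery (median per-TF Spearman ≥ 0.98) is the
acceptance surface for this simplification. FDR is taken across TFs within
each patient.

## Hub genes

The module subnetwork keeps adjacency entries above 0.4 (adjacency, not TOM;
a TOM variant would be a one-line change and a flag). Path-based
centralities use distances `1/weight`; closeness is harmonic so
disconnected subnetworks are well-defined; eigenvector centrality and
PageRank (damping 0.85) act on the weights. Robust Rank Aggregation: for
each gene the K = 5 normalized ranks give order-statistic p-values
`P(Beta(k, K−k+1) ≤ r_(k))`; `rho` is their minimum, multiplied by K
(Bonferroni over order statistics) and then by the module size (Bonferroni
across genes). Both correction layers are explicit because the source
description says only "Bonferroni corrected". The worked case — a gene
ranked first in all 3 of 10 — gives exactly rho 0.001, score 0.003,
adjusted 0.03.

## Drug connectivity

Bidirectional weighted K-S: hits increment by `|score|^p` (p = 1) normalized
over the query set, misses by `1/(n−t)`; the ES is the signed maximal
deviation. The combination rule is the classic connectivity-map convention:
same-sign ES pairs score 0, otherwise `(ES_up − ES_down)/2`. Two decisions:

* **One-directional queries** keep the mimic-positive sign convention
  (`ES_up`, or `−ES_down` for a down-only query). This matters because a
  dampened all-downregulated hub set is exactly the expected query.
* **Permutation p-values** are computed on the raw statistic
  `(ES_up − ES_down)/2` *without* the zeroing rule: zeroing puts an atom of
  probability ≈ ½ at score 0 under the null, which would make the p-values
  grossly non-uniform. With the raw statistic the null p-values pass a KS
  uniformity check.

For small queries (≈ 10 hub genes) against a panel containing a coherent
extreme block, the weighted statistic's permutation null is heavy-tailed —
random query sets catch high-|score| genes — which costs screening power
after multiplicity adjustment. The validation screens therefore use the
unweighted statistic; `weighted = TRUE` remains the function default.

## The synthetic cohort generator

`simulate_cohort()` plants, in order: a clinical table drawn from the
published cohort moments (DBP ~ Normal(74.78, 11.88²) truncated to
[40, 130] mmHg; SBP = DBP + a positive pulse-pressure offset so the two are
positively correlated; binary prevalences 20/38, 3/38, 7/38, 7/38); module
latent factors per patient, the first correlated with DBP at `trait_effect`
(default 0.6); gene loadings sized so that two genes of one module correlate
at `within_module_cor` (default 0.7) given `noise_sd` (default 0.5 log2
units); per-gene mean responses with the trait module planted as
downregulated (mean −1.5), mirroring the dampening phenotype; TF regulons in
the non-module gene pool with activities as patient-level standard normals,
repressor TFs (30%) wiring all targets with mode −1; and baseline
intensities uniform on 6–14 log2 units. The drug library covers a
978-gene landmark panel (the size of the common public landmark panel)
containing all trait-module genes; the mimic drug's signature is the planted
mean response itself and the reversal drug its exact negative, so their
correlation is −1 by construction, with myeloid cell-line labels for subset
filtering.

What the generator does **not** emulate: array technical artifacts, batch
effects, probe-level noise, heavy-tailed expression distributions,
correlated module factors, overlapping regulons, or the realistic sparsity
and redundancy of public drug-signature libraries. Passing tests therefore
establish that each stage recovers the structure it is designed to recover
under clean, correctly specified noise — not that effect sizes or error
rates transfer to real cohorts.

## Validation problem sizes

The test suite and `scripts/acceptance.R` run at sizes chosen to exercise
the study-scale geometry while completing in minutes: module recovery at
2000 genes × 38 patients over 25 seeds; consensus-network recovery at 1200
genes × 38 patients with 200 bootstrap iterations (nulls at 200 patients);
regulon recovery at 600 genes × 200 patients with 100 bootstraps; TF-null
calibration over 2000 NES draws; type-I calibration over 50 null cohorts;
drug screens with 50 drugs × 978 landmark genes and 1000 permutations. The
screen validation calls hubs on the planted trait module so that the
connectivity stage is tested in isolation from module–trait identification,
which has its own checks.

## Known limitations

* The static-cut-plus-kME module detector has no analogue of deep splitting;
  nested sub-modules of a large correlated block will not be separated.
* Histogram MI at n ≈ 38 patients has 2 bins and cannot discriminate strong
  from moderate dependence; regulon inference on cohorts that small should
  be interpreted as a screen, not an estimate.
* The consensus-network null behaves at larger cohorts; at n = 38 chance
  inter-module correlations survive gene resampling (see above).
* TF-activity inference omits pleiotropy/shadow correction, so TFs with
  heavily overlapping regulons can share credit.
* Connectivity p-values are per-drug permutation tests; no cross-signature
  normalization (tau-style) is attempted.
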