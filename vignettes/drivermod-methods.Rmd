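---
title: "Methods: module-network driver discovery, consensus subtyping and enhancer analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: module-network driver discovery, consensus subtyping and enhancer analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery of `drivermod`: the
models, the tunable parameters and their defaults, the numerical
conventions, and the design decisions taken where more than one
reasonable choice existed. It also describes exactly what the synthetic
cohort generator emulates — and what it does not — so that the package's
test results are read with the right scope.

## 1. The driver-discovery model

The premise is that a real driver alteration propagates: it shifts the
expression of many downstream genes, whereas a passenger does not. The
pipeline therefore scores candidate regulators by their ability to
predict the *condition-dependent mean expression* of co-expression
modules, rather than by recurrence alone. Candidates enter from five
platforms: recurrently mutated genes, copy-number amplified/deleted
genes, differentially methylated genes whose methylation predicts their
expression, miRNAs anti-correlated with annotated targets, and
transcription factors / literature genes represented by their expression
profiles. A gene may enter several times under different platform tags;
each (id, platform) entry carries its own covariate profile.

### 1.1 Two-way Gibbs sampling of co-expression modules

Input is the matrix of differentially expressed genes over tumor
samples, rows standardized to mean 0, SD 1 (module inference is run on
tumors because tumor-vs-normal shifts would otherwise dominate the
partition; the tumor-normal contrast is already consumed by the
differential-expression step). The model is a two-way block structure:
genes partition into modules, and within each module the samples
partition into blocks. The score of a configuration is the product over
(module, sample-block) cells of the Normal–Gamma marginal likelihood of
the cell's values,

$$\log p(x) = \log\Gamma(\alpha_n) - \log\Gamma(\alpha_0)
 + \alpha_0\log\beta_0 - \alpha_n\log\beta_n
 + \tfrac12\log\tfrac{\lambda_0}{\lambda_n} - \tfrac{n}{2}\log 2\pi,$$

with the usual conjugate updates of $(\lambda_n,\alpha_n,\beta_n)$. The
prior is $\mu_0 = 0$, $\lambda_0 = 0.1$, $\alpha_0 = 0.1$,
$\beta_0 = 0.1$: weak, symmetric, and appropriate for standardized data.
Each sweep resamples every gene's module (softmax over the exact score
change of the move) and every sample's block within each module. An
empty cell contributes marginal likelihood 1, so modules may empty and
refill — the number of modules passed to the sampler (`n_modules`,
default 10) is a capacity, not a commitment. Defaults: 10 chains × 100
sweeps, 2 sample blocks per module; each chain reports its best-scoring
sweep, and the per-iteration trace records the best-so-far score (hence
is non-decreasing by construction). The scoring function is exposed as
`partition_log_score()` so any configuration can be audited against
independent enumeration; the test suite does exactly that on 4-gene
instances, where all 15 gene partitions can be scored by hand.

Consensus across chains follows the tight-clustering idea: genes are
linked when they co-cluster in ≥ 80% of chains
(`co_clustering_threshold`), and connected components with ≥ 5 members
(`min_module_size`) become consensus modules; everything else is left
unassigned (module 0). The threshold trades coverage for purity — 0.8
keeps genes that most chains agree on while letting chain-specific
accidents fall out.

### 1.2 Regulation trees and regulator scores

Each module's "regulation program" is a binary tree over the module's
samples. A node splits by thresholding the module mean profile at its
exact 1-D two-means split (sorted scan minimizing within-group sum of
squares; threshold at the midpoint of the bounding pair). Regulator
profiles never define splits — only the module mean does — which
prevents a regulator from manufacturing its own association. Recursion
stops at `max_depth = 3`, at nodes with fewer than `2 * min_leaf`
(`min_leaf = 5`) samples, or when the node's module mean is constant.

At each internal node, every candidate regulator gets a *soft*
separation score: the absolute standardized mean difference $t$ of its
profile between the child blocks, mapped onto (0, 1) by
$s = 2\,\mathrm{logistic}(t) - 1$. This anchors no-separation at 0
(a profile constant across the node scores exactly 0) and saturates
smoothly; a profile with zero pooled within-child variance but different
child means — e.g. a binary mutation indicator split perfectly — scores
1, the maximal association. Significance is calibrated empirically: the
children are relabeled at random `n_rand = 100` times and the node p is
`(1 + #{random ≥ observed}) / (n_rand + 1)`, so the smallest attainable
p is ~0.01 and the null is the node's own split geometry.

The regulator-to-module score sums, over nodes where the regulator's
empirical p ≤ 0.05, the node weight (fraction of module samples at the
node) times the node score; the summed score adds this over modules.
Drivers are the union of (a) per module, the top
$\lceil 0.01 R\rceil$ regulators by module score, and (b) the top
$\lceil 0.10 R\rceil$ by summed score, where $R$ is the number of
candidate entries. Ceiling counts keep small candidate sets selecting at
least one; boundary ties are all included; zero scores are never
selected. Both quantiles are parameters (`per_module_q`, `global_q`) and
selection is monotone in each. Single-platform comparisons
(`run_single_platform`) restrict the scored entries to one platform's
tags and re-apply selection; because splits depend only on the module
mean, this is identical to running the whole pipeline with only that
platform's candidates.

### 1.3 Candidate selectors

* **Differential expression** — per-gene Welch t test (the unequal
  variance form is the safer default when tumor variance exceeds normal
  variance) with BH adjustment; q < 0.05 flags a gene. Zero-variance
  genes are flagged degenerate with p = 1. All BH corrections in the
  package route through one wrapper (`adjust_bh`) around
  `stats::p.adjust`.
* **Methylation** — a simplified beta-mixture screen: per gene, a 1–3
  component Gaussian mixture (BIC-selected, `mclust`) is fitted to tumor
  beta values, falling back to the logit scale when the fit on beta is
  unstable. A gene is hyper-/hypo-methylated when some component mean
  deviates from the normal-tissue mean by ≥ `min_delta_beta = 0.1`, and
  *transcriptionally predictive* when beta and expression are negatively
  Spearman-correlated across tumors at BH q < 0.05. Both filters must
  pass.
* **miRNA** — Spearman correlation for each annotated miRNA–target pair;
  pairs with rho < 0 and BH q < 0.05 are kept, and a miRNA is a
  candidate if it retains any pair. Positive correlations are excluded
  regardless of significance. Exact Spearman p-values are used for n ≤ 9
  (no ties), the t approximation otherwise.
* **Mutation / CNV** — external significance calls (precomputed lists
  from covariate-aware callers) are accepted as the faithful path for
  real cohorts; for synthetic runs a frequency surrogate applies:
  mutated in ≥ 2% of tumors, copy-number state ≥ +1 (≤ −1) in ≥ 10%. A
  gene passing both CNV thresholds appears in both lists, deliberately.

## 2. COCA subtyping

Level one clusters each platform's driver-feature matrix by subsampled
consensus clustering: 100 resamples of 80% of samples, base clusterer
NMF (hand-rolled Lee–Seung multiplicative updates; labels are the argmax
coefficient rows) when the matrix is non-negative — methylation beta,
raw expression — and k-means on standardized features otherwise. The
consensus matrix holds co-clustering frequencies among co-sampled pairs;
k ∈ 2..6 is chosen by the cophenetic correlation between 1 − consensus
and its average-linkage dendrogram, and final labels cut that dendrogram
at k.

Level two encodes all platform labels as a binary sample × cluster
indicator matrix (samples missing a platform get an all-zero block
rather than exclusion) and consensus-clusters it over k ∈ 2..8. Here the
base clusterer is average-linkage hierarchical clustering rather than
k-means: when k exceeds the true number of classes, hierarchical cutting
peels off outliers while k-means bisects tight groups differently in
every resample, degrading the consensus matrix and inflating the CDF
area gain at every k — which defeats model selection. The subclass count
is the largest k whose relative delta-area of the consensus CDF exceeds
0.025, the convention of the consensus-clustering literature; final
subclasses cut the chosen consensus matrix. With a single platform, COCA
returns that platform's labels unchanged.

Survival uses `survival::survfit`/`survdiff` behind `kaplan_meier()` and
`logrank_test()` (with the no-events case defined as statistic 0, p = 1).
Clinical association uses Fisher's exact test for categorical variables
(Monte-Carlo fallback for large tables) and a one-way ANOVA F test for
continuous ones — one-way because the association examined is variable ~
subclass — with BH correction across variables.

## 3. Enhancer and chromatin analysis

All interval logic is 0-based half-open, enforced by `signal_track()`
(uniform width, sorted, non-overlapping) and carried through
GenomicRanges internally; `[a,b)` and `[b,c)` never overlap. Tracks are
quantile-normalized (rank-wise means of order statistics, ties averaged,
via limma) so all output tracks share one distribution. Windows
overlapping ENCODE-style blacklists or promoters by ≥ 1 bp are excluded;
when no promoter file is supplied, TSS ± 2 kb is a reasonable stand-in.

A mark is "present" in a window when its value reaches the 75th
percentile of the track's nonzero values (configurable absolute
threshold) — scale-free and robust to sequencing depth. Both marks ⇒
strong enhancer; H3K4me1 alone ⇒ weak; H3K27ac alone is *not* an
enhancer. Adjacent same-class windows merge into regions. Differential
status is per window — gain if `(tumor + 1) / (normal + 1) ≥ 2`, loss
symmetrically, inclusive at the boundary — with the pseudocount guarding
division by zero; merging follows calling.

Gene association uses basal-plus-extension regulatory domains: basal =
5 kb upstream / 1 kb downstream of the TSS (strand-oriented), each side
extended outward by up to 20 kb *measured from the basal edge*, clipped
at the nearest neighboring gene's basal domain and at coordinate 0. The
"from the basal edge" convention is chosen so that the documented
invariant — extension ≤ 20 kb per side — holds exactly; a domain always
contains its own basal interval and never invades a neighbor's.
Chromatin states E1–E12 are active, E13–E18 inactive, and any other
label is an error rather than a silent NA.

Driver attribution follows two separately reported (possibly
overlapping) rules: genome-explained = down-regulated with mutation,
hypermethylation or deletion, or up-regulated with mutation or
amplification; enhancer-explained = down with enhancer loss in the
domain, or up with enhancer gain.

## 4. Downstream statistics

* **ssGSEA** — genes ranked by expression descending; the running sum
  gains $|v|^{0.75}$ (normalized over in-set genes) at set genes and
  drops $1/(N - n_{set})$ elsewhere; the ES integrates the running sum.
  The exponent 0.75 is the single-sample convention; at exponent 0 the
  score is rank-only and invariant to monotone transformations.
* **E2F × TP53 subgroups** — the E2F score is the mean of standardized
  E2F1/E2F2 rows, split at the cohort median (an explicit choice; the
  median guarantees balanced E2Fh/E2Fl arms), crossed with TP53 mutation
  status; pairwise Wilcoxon rank-sum tests compare a supplied pathway-ES
  vector across groups.
* **Mutual exclusivity** — one-sided binomial: under independence the
  co-occurrence probability is the product of marginal frequencies;
  p = P(X ≤ observed overlap). A margin-preserving permutation
  alternative is available behind `method = "permutation"`; the binomial
  form is the default because it is the directly stated test. The p is
  monotone in the overlap at fixed margins.
* **ORA** — one-sided hypergeometric upper tail per set, BH across sets;
  sets disjoint from the background are skipped.
* **Rank tests** — exact Wilcoxon when both groups have ≤ 8 values (no
  ties), normal approximation otherwise; chi-square without continuity
  correction.

## 5. The synthetic cohort generator

`generate_cohort()` plants, per module, a regulator from a configured
platform mix. Expression of a module gene in tumor $s$ is

$$x_{gs} = b_g + d\,\sigma_m + e\,a_m(s) + \varepsilon_{gs},$$

with gene baseline $b_g$, tumor-vs-normal shift $d$ (default = effect
size) signed by the module's regulator direction $\sigma_m$ (silencing
and repression drive their module down — the coherent coupling, and the
one that keeps the differential-expression step's power contract),
activation $a_m$ realized per platform — mutation indicator in 30% of
tumors (deliberately low, the regime where frequency-only mutation
analysis fails), CNV state/2 in 40%, methylation silencing indicator
(negative) in 50%, miRNA overexpression (negative) in 50%, TF expression
as a continuous standard-normal profile — and Gaussian noise
$\varepsilon$. Methylation is generated on the logit scale and
inverse-transformed, so beta values cannot leave [0, 1]; CNV states stay
in {−2..2} by construction. Decoy regulators (default 8 per genomic
platform plus 5 decoy TFs) carry alterations with no downstream effect,
giving precision something to fail on. Cis effects are planted for CNV,
methylation and TF regulators so the platform selectors can find them.
One global seed derives independent per-stage seeds, so any stage can be
regenerated alone and identical configurations are byte-identical.

`generate_signal_tracks()` shares a log-normal per-window baseline
between tumor and normal, floors it at 10 (windows emulate candidate
regulatory regions with appreciable occupancy; an unbounded low tail
would make a planted fold unidentifiable against the pseudocount, in
conflict with the generator's contract that noise-free planted events
are recoverable at threshold 2), multiplies gain windows and divides
loss windows by the planted fold in the tumor track, and applies
independent multiplicative log-normal noise at the requested coefficient
of variation. `generate_survival()` draws exponential event times at
per-subtype rate baseline × HR with independent uniform censoring.
`generate_subtype_platforms()` gives each platform a (possibly merged)
view of the true subtypes — the default four platforms see the three
distinct 2-way merges of 4 subtypes — with class-center separation set
by an SNR parameter.

**What passing tests do and do not show.** The generator produces
Gaussian noise, independent genes within modules after conditioning on
the activation, perfectly aligned samples across platforms, no batch
structure, no mixed tumor purity, no correlated passenger alterations,
and binary-ish activation profiles. Recovery of planted structure under
these conditions demonstrates the machinery is correct and calibrated —
the Gibbs score matches enumeration, selection rules behave, type-I
error is nominal — not that real-cohort driver lists at any particular
FDR will be as clean. Real data adds heavy tails, probe-level
methylation structure, CNV segmentation noise and batch effects that
this generator deliberately does not model (batch correction is assumed
upstream).

## 6. Problem sizes and numerical conventions

The test suite and acceptance script size the simulations for a single
CPU: module recovery uses 200 clustered genes (5 × 40) over 60 tumors
with 10 chains × 100 sweeps, 10 seeds; driver recovery uses the default
cohort (5 modules, one planted regulator each, ~35 decoys) over 10
seeds; COCA uses 120 samples × 4 platforms over 10 seeds; the log-rank
null uses 1000 replicates at n = 50 per group. These are the package's
reference conditions, chosen to finish in minutes while leaving the
statistical margins wide.

Numerical conventions worth knowing: empty cells score log-likelihood 0
in the Gibbs sampler; two-means split thresholds sit at midpoints, with
ties resolved by the sorted scan; empirical p-values use the add-one
form and can never be 0; `consensus_cluster_platform` treats a degenerate
(all-equal) consensus as cophenetic 0; `quantile_normalize` averages
ties; fold-change calls are inclusive at the threshold; the pseudocount
is 1.0; `signal_track` rejects negative values, non-uniform widths and
overlaps outright. Reproducibility is part of every contract: the same
seed and configuration produce bitwise-identical matrices, chains and
calls.

## 7. Known limitations

* The sampler uses a fixed module capacity rather than a nonparametric
  prior; capacity well above the expected module count costs little and
  is the recommended setting.
* The regulation-tree empirical p is calibrated per node, not
  family-wise across nodes or modules; the per-module and global
  selection quantiles — not the node p — are the operative multiplicity
  control, mirroring the top-k driver definition.
* The simplified methylation screen fits mixtures per gene independently
  and does not model probe-level structure or copy-number contamination
  of beta values.
* COCA's delta-area threshold (0.025) is a convention; on weakly
  separated cohorts the chosen k is sensitive to it, and the per-k CDF
  areas are returned so the curve can be inspected.
* Enhancer analysis expects one tumor and one normal track (cell-line vs
  tissue in the motivating use); there is no replicate-aware variance
  model.
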