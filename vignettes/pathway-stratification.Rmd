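---
title: "Pathway-utilization stratification: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-utilization stratification: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathstrat)
```

pathstrat stratifies a bulk expression cohort by which pathways each tumor
appears to *use*, rather than by marker-gene subtypes. The chain is: score
every sample against every gene set (per-sample preranked GSEA against the
cohort mean), cluster samples on the resulting enrichment profile, distill
the profile into small directional gene signatures via PCA contributions,
and carry those signatures into survival comparison, single-cell scoring,
coexpression modules and regulator annotation. This vignette explains each
model, the tunable parameters, and the numerical decisions — including the
places where the design was genuinely open and what we chose.

## Per-sample enrichment

For sample $s$ and gene $g$ the ranking statistic is

$$ t_{gs} = x_{gs} - \bar{x}_{g\cdot}, $$

the sample's log2 expression minus the cohort mean *including the sample
itself*. That is the simplest reading of "compare each sample with the
cohort average"; excluding the sample would rescale the statistic by
$n/(n-1)$ and change nothing downstream except at very small $n$. Ties in
the ranking are broken by gene symbol so every run produces the same order.

The enrichment score is the classic weighted Kolmogorov–Smirnov statistic:
walking the ranked list, genes in the set add $|t|^p / \sum_{hits} |t|^p$
and genes outside subtract $1/(N - N_{hit})$; the ES is the largest
excursion of this running sum, signed. Defaults: weight $p = 1$ (GSEA's
standard); $p = 0$ is retained because its closed forms (single hit at the
top gives ES = 1) anchor the tests. Two numerical details worth knowing:

* **Tie rule.** When the positive peak and the negative trough tie in
  magnitude the positive side wins. Ties are common at $p = 0$ (the running
  sum lives on a lattice), and the comparison is made with a $10^{-12}$
  tolerance so that the $O(N)$ running-sum path and the $O(N_{hit})$
  hit-position shortcut used during permutations always agree.
* **Degenerate weights.** If every in-set $|t|$ is zero (a sample exactly at
  the cohort mean) the hit increments fall back to equal weights rather
  than dividing by zero.

**Normalization.** Each ES is divided by the mean magnitude of same-sign
null scores obtained by redrawing random gene sets of the same size from
the ranked list (*gene-label* permutation, default `n_perm = 1000`,
seeded). Phenotype permutation is not an option here because each sample is
scored alone. The choice is documented rather than inferred: single-sample
GSEA variants differ on this point, and gene-label permutation is the one
that is well defined per sample. A two-sided empirical p-value
$(1 + \#\{|ES_{null}| \ge |ES|\})/(n_{perm}+1)$ accompanies every score;
on null data (no planted effect) its rejection rate at $\alpha = 0.05$ sits
inside [0.03, 0.07], which the acceptance suite verifies. Sets with no gene
in the matrix are *unscored* (`NA`), never zero.

## Signatures from PCA contributions

The samples-by-sets NES matrix is decomposed by PCA with variables
(gene sets) centered and scaled — correlation PCA — because NES magnitudes
vary systematically with set size. A set's *contribution* to component $k$
is $100 \cdot \ell_{jk}^2 / \sum_j \ell_{jk}^2$ (percent of the component);
its *direction* is the sign of its loading. Component signs are fixed
deterministically (the largest-|loading| variable is made positive), so
P/N labels are stable across runs; flipping a component's sign swaps the P
and N signatures exactly.

A signature for one component/direction pools the **top 20** contributing
sets of that direction (ties by contribution, then name) and keeps genes
present in **at least 5** of them. Both thresholds are configurable
(`top_n`, `min_overlap`); 20/5 are the conventional defaults this analysis
was built around. Names follow
`<datasetCode><collectionCode>-<component><P|N>` — e.g. `T2-1N` is a
TCGA-coded dataset (`T`), canonical collection (`2`), component 1,
negative direction. One open choice: "top contributing sets in a
direction" could also rank by signed loading magnitude instead of
contribution within the signed subset; we rank by contribution, which is
the quantity the decomposition reports.

## Consensus clustering

Monti-style resampling: subsample 80% of samples without replacement
(`n_resamples = 250`), k-means each subsample (k-means++ seeding — base
`kmeans` offers only random starts), and accumulate how often each pair
co-clusters, normalized by how often it was co-sampled. The number of
clusters is chosen by minimizing PAC, the proportion of off-diagonal
consensus entries strictly inside (0.1, 0.9); ties go to the smaller k.
Final labels come from average-linkage hierarchical clustering of
$1 - \text{consensus}$, per the original consensus procedure. The NMF
alternative shifts the profile to non-negative by subtracting its global
minimum (NES can be negative; this is a modeling choice, not a
transformation with biological meaning) and runs multiplicative-update
factorization, best of 20 restarts. A random forest trained to predict the
final labels from the profile reports out-of-bag accuracy as a robustness
check.

## Survival

Kaplan–Meier and the Mantel–Cox log-rank test are implemented directly
(product-limit estimator; per-event-time hypergeometric variance), with
the `survival` package serving as an independent reference in the test
suite — the two agree to $10^{-8}$ on random tables. The reported median
is the first time $S(t) \le 0.5$. Pairwise comparisons across clusters are
adjusted with Benjamini–Hochberg by default. The literature this package
serves sometimes says "Bonferroni–Hochberg", which is not a method; we
read it as Benjamini–Hochberg and expose `method = "bonferroni"` for the
stricter reading.

The limiting-dilution estimator assumes the single-hit Poisson model: a
well seeded with $d$ cells is negative with probability $e^{-fd}$.
Frequency $f$ is fit by complementary log-log binomial regression with
unit slope on $\log d$; with one dose this collapses to the closed form
$f = -\log(\text{neg}/\text{wells})/d$. Saturated assays (all wells
negative, or all positive) sit on the likelihood boundary and are flagged
instead of given a CI.

## Single-cell scores

A cell's score for a gene set is the mean log expression of the set's
detected genes minus the mean over *all* detected genes in that cell — so
the all-detected-genes set scores exactly 0 everywhere, and adding a
constant to a cell changes nothing. "Detected" defaults to dataset-wide
(nonzero in at least one cell); per-cell detection is available by flag
(`detection = "cell"`) because public single-cell scores differ on this
and the source convention is not stated. Signature–signature Pearson
correlations across cells carry raw p below the diagonal and BH-adjusted p
above (the "dual diagonal" display); signatures are grouped by
average-linkage clustering of $1 - r$, default 3 groups.

## Coexpression modules

A deliberately compact WGCNA-style core: unsigned adjacency $|r|^\beta$,
topological overlap, average-linkage tree, **static** cut at height 0.99,
modules below `min_module_size = 10` left unassigned. Static rather than
dynamic tree cut keeps the procedure deterministic and dependency-free at
desk scale; it will merge adjacent modules that the dynamic cut would
split. $\beta$ is auto-selected as the smallest power in 1..20 whose
connectivity distribution fits a scale-free law at $R^2 \ge 0.8$ —
with one guard: candidate powers must keep mean connectivity at least 1.
Planted-block experiments showed that without the guard the selector can
run to powers that collapse the network (mean connectivity below 0.5) and
fragment real modules; blocks are simply not scale-free at low powers.
Eigengenes are first principal components, unit length, sign-fixed to
correlate positively with the module's mean expression; hub genes are
ranked by kME with sub-$10^{-10}$ differences treated as ties (broken by
symbol).

## Differential expression, ORA, regulators

Cluster-versus-rest contrasts use Welch's t-test per gene (no method is
canonical here; Welch is the conservative default that needs no
equal-variance assumption), BH across genes. Term enrichment is the
upper-tail hypergeometric test. The upstream-regulator component is a
transparent stand-in for proprietary curated tools: per regulon, ORA of
its targets in the signature, plus — when targets carry `+`/`-` signs — a
direction score $(\text{concordant} - \text{discordant})/\sqrt{n}$ over
the overlapping targets, thresholded at $|z| \ge 2$ and adjusted
$p < 0.05$ for an activated/inhibited call. It makes no claim of
reproducing any curated knowledge base; regulons are entirely
user-supplied.

## The synthetic cohort generator

Every downstream stage is exercised on data with planted, recoverable
structure. `simulate_bulk()` draws Gaussian log2 expression around
per-gene means, then shifts each cluster's program genes by `effect`
(down-programs by `-effect`); survival is exponential with per-cluster
hazards and independent uniform right-censoring. The defaults *are* the
study conditions the tests assume: 2000 genes, 60 samples, 3 clusters, one
50-gene program per cluster, effect 2, noise SD 1, hazards 0.04–0.10,
censoring 20%.

Two generator features deserve explanation:

* **Redundant planted sets.** Each program is represented by
  `sets_per_program = 8` gene sets, each covering a random 80% of the
  program. Curated pathway collections are redundant in exactly this way,
  and the redundancy is what makes consensus-of-top-sets signature
  synthesis meaningful: a gene can only clear the `min_overlap = 5` bar if
  several source sets agree on it.
* **Decoy sets** of matched size, drawn from the whole gene pool, so that
  enrichment specificity (planted sets outrank decoys) is a testable
  claim.

Gaussian log-expression is used rather than counts: every consumer in the
chain works on normalized log data, so count-level realism adds test cost
without test power. The single-cell generator likewise plants state
programs with uniform dropout; it does not model negative-binomial counts,
batch effects or doublets. Passing tests therefore demonstrate that the
machinery recovers the structure it is designed to detect under clean
planted conditions — not that real cohorts are this well behaved: real
data add heavier tails, correlated noise, unbalanced clusters and
partially overlapping programs, all of which can only degrade, not bias,
the planted-recovery checks.

## Reproducibility and problem sizes

All generators and stochastic stages are pure functions of their seeds;
`run_pipeline()` derives a per-stage sub-seed from the global seed and the
stage name, so stages can be reordered or disabled without reshuffling
seeds, and two runs of one config produce byte-identical stage outputs.
The test and acceptance suites run the full chain at desk scale — 60
samples, 2000 genes, ~60 gene sets, 400 cells, 500 permutations — chosen
as the smallest sizes at which the planted-recovery claims (ARI 1.0 at
effect 2, AUC $\ge$ 0.9 at 30% dropout, type-I rates inside [0.03, 0.07])
are comfortably stable across seeds; a full run takes on the order of half
a minute on one CPU.

## Known limitations

* Classic-vs-single-sample GSEA ambiguity: the per-sample ranking plus
  gene-label permutation used here is one defensible reading, not the only
  one; ssGSEA-style rank-weighted scores would differ in scale.
* PAC-based k selection inherits PAC's known bias toward cleaner, larger
  k at small sample sizes; the PAC curve is reported so users can inspect
  the decision.
* The static tree cut merges close modules; 26-module-scale dissection of
  a real cohort would want the dynamic hybrid cut of canonical WGCNA.
* The regulator stand-in ranks overlap enrichment only; it cannot
  reproduce curated causal-network z-scores.
* ANOVA-style wet-lab endpoint analysis is out of scope; the survival
  module covers the cohort-level clinical comparison only.
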