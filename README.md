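# pathstrat

Pathway-utilization stratification of tumor expression cohorts.

Marker-gene subtypes often fail to predict which pathways a tumor actually
relies on. `pathstrat` takes the complementary route for bulk
transcriptomics (with single-cell follow-up): score every **sample**
against every **gene set**, cluster patients on that enrichment profile,
distill the profile into small directional gene signatures, and test
whether the resulting strata differ clinically. It is written for
computational biologists analyzing log-normalized expression cohorts
(e.g. glioblastoma) against curated pathway collections (GMT), and for
anyone who needs its individual pieces — per-sample preranked GSEA,
consensus clustering, Kaplan–Meier/log-rank, per-cell signature scores,
WGCNA-style modules, or limiting-dilution frequency estimation — as
tested, seeded building blocks.

## The model in brief

* **Per-sample enrichment.** Sample *s* ranks genes by
  $t_{gs} = x_{gs} - \bar{x}_{g\cdot}$ (log2 expression minus cohort
  mean). Each gene set gets the weighted Kolmogorov–Smirnov enrichment
  score (weight $p = 1$): hits add $|t|^p/\sum_{hits}|t|^p$, misses
  subtract $1/(N - N_{hit})$; ES is the signed maximum excursion. A
  gene-label permutation null (random same-size sets) yields
  $NES = ES / \overline{|ES_{null}^{same\ sign}|}$ and an empirical
  p-value.
* **Signatures.** PCA of the samples-by-sets NES matrix (correlation
  PCA); a set's contribution to a component is its squared loading as a
  percent. The top 20 contributors in one direction are pooled and genes
  present in ≥ 5 of them form the signature, named
  `<dataset><collection>-<component><P|N>` (e.g. `T2-1N`).
* **Strata.** Monti consensus clustering (k-means inner loop, PAC-minimal
  k, hierarchical final labels), an NMF cross-check, random-forest
  robustness, then log-rank survival comparison with BH-adjusted pairwise
  tests.
* **Follow-up.** Per-cell signature scores (set mean minus detected-gene
  mean), correlation maps with raw/FDR dual significance; coexpression
  modules ($|r|^\beta$ adjacency, TOM, static cut) with kME hub genes;
  Welch differential expression; hypergeometric ORA; a transparent
  upstream-regulator stand-in; single-hit Poisson limiting-dilution
  frequencies.

A seeded synthetic-data generator (`simulate_bulk()`,
`simulate_single_cell()`, `simulate_coexpression()`) plants known
clusters, programs, hazards and cell states so the whole chain is testable
without external data.

## Worked example

```r
library(pathstrat)

sim  <- simulate_bulk(simulation_config(seed = 42))     # 2000 genes x 60 samples, 3 planted clusters
prof <- normalize_es(sim$expression, sim$collection, n_perm = 500, seed = 42)
prof
#> <enrichment_profile> 60 samples x 54 gene sets (n_perm = 500, weight = 1)

cons <- consensus_cluster(prof, k_range = 2:6, seed = 42)
cons
#> <consensus_result> chosen k = 3 over k in {2, 3, 4, 5, 6}
#>   PAC: k2=0.678  k3=0.000  k4=0.244  k5=0.291  k6=0.302
#>   cluster sizes: 20, 20, 20
ari(cons$labels, sim$truth$labels)
#> [1] 1

pc   <- pca_decompose(prof)
sigs <- synthesize_signatures(pc, sim$collection, dataset_code = "T")
sigs[[1]]
#> <gene_signature> TS-1P: 50 genes from 20 source sets (PC1, positive)

pairwise_logrank_adjusted(sim$clinical, labels = cons$labels)
#> # A tibble: 3 x 5
#>   group1 group2 chi_square       p  p_adj
#>    <int>  <int>      <dbl>   <dbl>  <dbl>
#> 1      1      2     2.29   0.130   0.195
#> 2      1      3     0.0297 0.863   0.863
#> 3      2      3     6.87   0.00875 0.0263
```

Reading the output: PAC drops to exactly 0 at k = 3 — under resampling,
every pair of samples either always or never co-clusters — so consensus
clustering selects three strata, which match the planted labels perfectly
(adjusted Rand index 1). The first synthesized signature recovers the
50-gene program planted in one cluster from the 20 top-contributing gene
sets. The pairwise log-rank table compares the strata's survival: with
planted hazards 0.04/0.07/0.10 and only 20 patients per stratum, the
extreme pair (clusters 2 vs 3 here, adjusted p = 0.026) separates while
adjacent hazards do not — survival contrast at this cohort size is real
but modest, as expected.

Every fitted object has `tidy()` / `glance()` and `autoplot()` methods
(`plot_km()`, `plot_consensus_matrix()` for multi-group views), and
`run_pipeline()` drives the whole chain from one YAML config, writing
plain TSV/GMT/JSON stage outputs plus a manifest with per-stage seeds and
digests. A thin CLI over the same functions ships in
`inst/scripts/pathstrat.R`.

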