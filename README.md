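# glycoindex

Glycolysis-index analysis of bulk brain expression data: derive a consensus
"core" glycolysis gene set across several case/control datasets, score every
sample with a single-sample GSEA (ssGSEA) glycolysis index, and relate the
index to differential expression, pathway enrichment, brain cell-type
content, and a consensus co-expression network.

The package is aimed at transcriptomics analysts working with normalized,
log2-scale expression matrices from multiple cohorts or brain regions
(e.g. postmortem case/control microarray panels) who want a reusable,
fully offline-testable implementation of this analysis style.

## What it computes

**Core gene set.** For each dataset, genes are ranked by the case-vs-control
signal-to-noise ratio r_g = (mu_case − mu_ctrl) / (sd_case + sd_ctrl) (with
the classic variance floor), and each glycolysis gene set S is scored with
the weighted Kolmogorov–Smirnov running sum

ES(S) = the signed largest deviation of P_hit(i) − P_miss(i),
P_hit(i) = Σ_{j≤i, g_j∈S} |r_j|^p / Σ_{g∈S} |r_g|^p,
P_miss(i) = #{j≤i, g_j∉S} / (N − N_hit),

with permutation NES/p-values and Benjamini–Hochberg FDR. The *leading
edge* of a downregulated set (ES < 0) is the set members ranked at or after
the trough. Genes that are leading-edge members in at least half of the
datasets (for significant, downregulated sets) form the **core glycolysis
gene set**.

**Glycolysis index.** Each sample's index is its ssGSEA enrichment score for
the core set: with genes ranked within the sample and v = rank from the
bottom,

ES = Σ_i [ P_in^α(i) − P_out(i) ],  P_in^α(i) = Σ_{j≤i, g_j∈S} v_j^α / Σ_{g∈S} v_g^α,

the integrated (summed) difference with α = 0.25. The index is rank-based,
so it is invariant to monotone transforms of a sample's values.

**Downstream stages.** Samples are median-split on the index within each
region; differential expression uses per-gene OLS with region, sex and a
df-1 natural age spline as covariates and empirical-Bayes variance
moderation (posterior variance (d0·s0² + d_g·s_g²)/(d0 + d_g), moment
estimation of d0 and s0² on log s²); DEGs are filtered at FDR < 0.05 and
|log2FC| > 0.5 (both strict); over-representation uses one-sided
hypergeometric tails against the genes measured in all datasets; cell-type
content comes from marker-set ssGSEA scores and non-negative least-squares
deconvolution against a signature matrix; and the consensus network keeps
glycolysis–marker gene pairs supported by at least 4 of 5 evidence channels
(Spearman FDR < 0.05 in each of 4 datasets, PPI score > 0.7) with consistent
correlation signs.

A synthetic-data module (`simulation_config()`, `make_fixture_bundle()`)
generates multi-region case/control datasets with planted downregulation,
covariate effects, planted gene–gene correlations and cell-type mixtures, so
every stage is exercisable without any download.

## Worked example

```r
library(glycoindex)

cfg <- simulation_config(n_genes = 800, n_per_group = 20, seed = 42)
bundle_dir <- file.path(tempdir(), "glyco_demo")
pcfg <- simulate_fixture_bundle(cfg, bundle_dir, n_perm = 500)
res <- run_pipeline(pcfg)
#> [glycoindex] stage 1/8: GSEA per dataset
#> ...
#> [glycoindex] done: 18 stage outputs + manifest.json

res$core
#> CoreGeneSet: 33 genes supported by >= 2 datasets
#>   GLY001, GLY002, GLY003, GLY004, GLY005, GLY006, GLY007, ...

grp <- do.call(rbind, lapply(res$datasets, `[[`, "metadata"))$group
compare_groups(res$index$scores, grp)
#> AssociationResult: statistic = 308, p = 5.75e-23, directed log p = -22.2

res$network
#> ConsensusNetwork: 10 edges over 20 nodes (min_support = 4 of 5 channels)

head(res$ora, 3)[, 1:7]
#>               term  k  K  n   N      p_value          fdr
#> 1 GLYCOLYSIS_SET_1 23 42 29 800 1.108918e-27 7.762426e-27
#> 2 GLYCOLYSIS_SET_2 21 37 29 800 3.402573e-25 1.190901e-24
#> 3 GLYCOLYSIS_SET_3 15 30 29 800 3.954249e-16 9.226580e-16
```

Reading the output: the pooled core set (33 genes here) contains the 30
genes the simulation downregulated in cases plus a few set neighbours; the
negative directed log p says the glycolysis index is lower in the case
group, as planted; the consensus network recovers the 10 planted
glycolysis–marker correlations; and the over-representation table shows the
overlapping DEGs are concentrated in the glycolysis-like sets, with the hit
counts (k of K term genes among n query genes in an N-gene background)
driving the hypergeometric p-values.

All intermediate tables (GSEA results, core-set support, per-sample index
with split labels, both DE contrasts, DEG lists, ORA, marker scores,
abundances, association tables, network edges) are written under
`pcfg$out_dir` as TSV plus a JSON manifest.

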