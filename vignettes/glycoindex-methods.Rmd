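---
title: "Methods: the glycolysis index and its downstream analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the glycolysis index and its downstream analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures the package implements, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical and design choices that were genuinely open.

## The analysis in one paragraph

Given several case/control expression datasets on a shared gene universe
(typically one per brain region), the package (1) runs gene set enrichment
analysis (GSEA) of a collection of glycolysis gene sets against each
dataset's case-vs-control ranking, (2) pools the leading-edge genes of
significantly downregulated sets across datasets into a consensus *core
glycolysis gene set*, (3) scores every sample with a single-sample GSEA
(ssGSEA) enrichment score of that core set — the *glycolysis index*, (4)
median-splits samples on the index within each region and runs two
covariate-adjusted moderated differential-expression contrasts
(case-vs-control and high-vs-low index), intersecting their DEG lists, (5)
tests the intersection for over-represented terms against the genes measured
in all datasets, (6) quantifies brain cell-type content by marker-set ssGSEA
and non-negative least-squares (NNLS) deconvolution and associates it with
group and index, and (7) assembles a consensus network of glycolysis–marker
gene pairs supported by co-expression in multiple datasets plus
protein–protein interaction (PPI) evidence.

## GSEA: ranking, running score, significance

Genes are ranked by the signal-to-noise ratio
\[(\mu_{case}-\mu_{ctrl})/(\sigma_{case}+\sigma_{ctrl}),\]
with each group's standard deviation floored at
\(\max(0.2\,|\mu|,\,0.2)\). The floor is the classic GSEA convention: it
keeps near-constant genes from producing huge ratios out of numerical
noise. A moderated-t ranking is available as an alternative for small
groups (it borrows variance information across genes). The method that
produced the expression data names no ranking metric, so the signal-to-noise
default is a convention, not a reproduction.

The running enrichment score is the weighted Kolmogorov–Smirnov form: hits
contribute \(|r|^p\) (normalized over the set), misses \(1/(N-N_{hit})\),
and the enrichment score (ES) is the signed largest absolute deviation of
the running sum. Defaults: weight \(p = 1\) (the classic weighted
statistic), earliest position on extremum ties. Ties in the ranking itself
are broken by gene symbol, ascending, after sorting by metric descending —
this makes every result platform-independent and reproducible.

The leading edge of a positively enriched set is its members at or before
the peak; for a downregulated set (ES < 0) it is the members at or after the
trough, inclusive of the trough position (the standard convention).

Significance uses permutations. Two null schemes are implemented. The
default, gene permutation, redraws random sets of the same size over the
fixed ranking — cheap, and the behaviour of the fast GSEA backends commonly
used with collection-scale analyses. Phenotype permutation relabels samples
and re-ranks; it preserves gene–gene correlation and is available where
group sizes allow. The normalized ES divides the observed ES by the mean
|null ES| of matching sign, and
\[p = \frac{1 + \#\{\text{same-sign nulls with } |ES^*| \ge |ES|\}}{1 + \#\text{same-sign nulls}},\]
the add-one form that never returns zero. The source analysis states neither
the permutation count nor the scheme; `n_perm = 1000` and the gene scheme
are documented defaults, exposed in the configuration.

## Pooling the core gene set

A gene is "leading in dataset d" if it lies in the leading edge of at least
one gene set whose result in d is downregulated (ES < 0) and significant
(FDR ≤ 0.05 by default; the filter can be disabled because the original
procedure does not state one). Genes leading in at least `min_datasets`
(default 2, i.e. half of four datasets) distinct datasets form the core
set. Pooling is monotone: lowering `min_datasets` can only add genes.

## The glycolysis index (ssGSEA)

Within each sample, genes are ranked by expression (descending, ties broken
by symbol), and with \(v_j\) the rank-from-bottom of the gene at position
\(j\),
\[ES = \sum_{i=1}^{N}\Big[P_{in}^{\alpha}(i) - P_{out}(i)\Big],\qquad
P_{in}^{\alpha}(i) = \frac{\sum_{j\le i,\,g_j\in S} v_j^{\alpha}}{\sum_{g\in S} v_g^{\alpha}},\]
the *integrated* (summed) difference rather than the running-sum extremum —
the Barbie-style single-sample statistic. Defaults: \(\alpha = 0.25\) (the
common single-sample default) and **no** cross-sample normalization, so the
index of a sample is a pure function of that sample's ranks: scoring samples
singly or jointly gives identical values, and any monotone transform of a
sample leaves its score unchanged. Optional `normalize = TRUE` divides all
scores by their max–min range, the only cross-sample step; whether the
original index was range-normalized is not stated, so raw ES is the default.

Expression ties within a sample are broken by the same stable
(value descending, symbol ascending) rule instead of average ranks; this
keeps the weighted sum well-defined and deterministic at the cost of a
microscopic asymmetry between tied genes, negligible for continuous data.

The median split labels samples at or below their region's median index as
"low", the rest "high"; regions are split independently so level differences
between regions cannot leak into the labels. Ties go to "low".

## Differential expression

Each gene's log2 expression is fit by ordinary least squares on a shared
design: intercept, contrast indicator (case, or high-index), region dummies
(reference: first region alphabetically), sex dummy (M = 1), and a natural
cubic spline of age with one degree of freedom. With df = 1 and boundary
knots at the data range, the natural-spline basis is in fact a linear
function of age — the conventional low-risk encoding of a continuous
covariate; the df is exposed for users who want curvature. Reference levels
are fixed so coefficient signs are stable across runs.

Variance moderation follows the standard empirical-Bayes hierarchy: each
gene's residual variance \(s_g^2\) (on \(d_g\) df) is shrunk to
\[\tilde{s}_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\]
with \((d_0, s_0^2)\) estimated by method of moments on \(\log s_g^2\)
(digamma/trigamma identities; the trigamma inverse is solved by Newton
iteration to 1e-8). The moderated t uses \(d_0 + d_g\) degrees of freedom.
When the observed variances carry no excess dispersion beyond chi-square
sampling noise, \(d_0\) is capped at 1e6 and all posterior variances are set
to \(s_0^2\) exactly ("infinite" pooling). The implementation is checked
against the installed limma on simulated data in the test suite but does not
call it.

DEGs require FDR < 0.05 **and** |log2FC| > 0.5, both strict, matching the
printed thresholds; the two contrasts' DEG lists are intersected to give the
glycolysis-related DEGs.

One property worth flagging: Benjamini–Hochberg adjustment is *not* a fixed
point of itself. Re-adjusting already-adjusted values inflates them
(e.g. (0.1, 0.9) adjusts to (0.2, 0.9), which re-adjusts to (0.4, 0.9)),
because adjusted values are no longer raw p-values. The package applies BH
exactly once per test family.

## Over-representation analysis

One-sided hypergeometric tails \(P(X \ge k)\) for each term, with the term,
query and universe all restricted to an explicit background — the genes
measured in every dataset — and BH across tested terms. Terms without
background genes are skipped; query genes outside the background are dropped
with a warning. No term database ships with the package: annotations are
user-supplied GMT, which keeps results independent of database versions.

## Microenvironment

Marker-set ssGSEA gives a relative abundance proxy per cell type. NNLS
deconvolution regresses each sample's linear-scale expression
(\(2^x - 1\), matching the \(\log_2(x+1)\) loading convention of the mixture
generator) on the signature-matrix columns under non-negativity
(Lawson–Hanson via `pracma::lsqnonneg`); `relative` mode rescales
coefficients to sum to one, `absolute` returns raw coefficients, which scale
with overall expression. The heavyweight proprietary deconvolution suites
are deliberately not reimplemented; NNLS is a transparent stand-in with the
same signature-matrix interface.

Group differences use the two-sided Wilcoxon rank-sum test — exact when the
combined n is at most 20 and tie-free, otherwise the tie-corrected normal
approximation (the switch is documented because p-values near thresholds
depend on it) — summarized as a directed log p,
\(\mathrm{sign}(\mathrm{median}_{case}-\mathrm{median}_{ctrl})\cdot(-\log_{10} p)\).
Correlations with the index use Spearman's rho with the t approximation
\(t = \rho\sqrt{(n-2)/(1-\rho^2)}\) for all n, so behaviour does not jump
between exact and approximate regimes. Covariate-adjusted association fits
\(y \sim x + \text{covariates}\) by least squares or logistic IRLS (max 50
iterations, tolerance 1e-8) and reports the Wald statistic for x; perfect
separation is flagged rather than reported as a spuriously tiny p.

## Consensus network

For every glycolysis-gene × marker-gene pair, five evidence channels:
Spearman co-expression significant at FDR < 0.05 in each of the (typically
four) datasets — the BH family is per-dataset, matching the per-dataset
analysis — plus membership in the high-confidence PPI table (score > 0.7,
strictly; scores are accepted on the 0–1 scale, with the STRING integer 700
corresponding to 0.7). An edge is kept when at least `min_support = 4`
channels support it and all *significant* datasets agree in correlation
sign; non-significant datasets' signs are ignored (the literal reading of
the sign-consistency rule). PPI support carries no sign, so a pair needs at
least one significant dataset to have a defined sign; with `min_support = 4`
this is automatic. Pairs missing from a dataset count as an unsupported
channel there rather than being excluded, keeping the five-channel
arithmetic intact. Constant genes are untestable and excluded from the BH
denominator.

## The synthetic-data generator

`simulation_config()` defines a four-region case/control study on a shared
universe: a fixed 50-gene glycolysis-like block (GLY001–GLY050) plus filler
genes. Per region: per-gene baseline means ~ Normal(7, 1.5) on the log2
scale, i.i.d. Normal(0, `noise_sd`) residuals, the planted set shifted by
`effect_size` in cases, a linear age effect on a random 10% of genes and a
sex shift on 5%, ages Uniform(60, 95) (the disease's age range, without
claiming its empirical distribution), balanced sexes. Defaults — 30 planted
genes at −0.8 log2 units, noise sd 1.0, n = 30 per group per region — are
the package's standing study conditions, chosen once as a realistic
moderate-effect microarray scenario. Planted gene–gene correlations rebuild
the second gene's residuals as a ρ-weighted mixture of the first gene's
standardized residuals and fresh noise. Mixture samples are
signature-by-proportion products with multiplicative log-normal noise,
loaded as log2(x + 1). The seven synthetic gene sets are overlapping subsets
(sizes 10–40) of the glycolysis block with every block gene in at least two
sets, mimicking the heavy redundancy of curated glycolysis collections, so
leading-edge pooling faces realistic overlap.

What the generator does **not** emulate: empirical mean–variance
relationships of real arrays, probe-level artefacts, batch effects,
correlated gene modules beyond the planted pairs, count-data noise
(the Gaussian log-scale model reflects normalized microarray intensities,
not RNA-seq counts), and single-cell data. Passing tests therefore
demonstrate correctness of the machinery and its operating characteristics
under a clean Gaussian world — not performance on raw, batch-affected real
data.

## Numerical and interface choices

- Gene matching is case-sensitive exact string comparison; an optional
  uppercase-normalization step is deliberately absent by default.
- Missing expression values are rejected at load rather than imputed —
  silent imputation would contaminate rank-based scores.
- Duplicate gene symbols are collapsed by per-row median at load, the
  summarisation convention for probe-to-symbol mapping.
- Values are assumed log2-scale; only the DE and deconvolution stages care
  (rank-based stages are scale-agnostic). This is a documented contract,
  not auto-detected.
- All randomness flows from explicit integer seeds; per-region and per-set
  sub-seeds are derived deterministically, so every pipeline output is
  byte-identical across runs with the same configuration.
- Test and acceptance problem sizes (e.g. 2000-gene DE simulations,
  500–1000 permutations, 50-sample ssGSEA oracle sweeps) were chosen as the
  smallest sizes at which the operating characteristics are stable.

## Known limitations

- Gene-permutation GSEA p-values ignore inter-gene correlation; phenotype
  permutation is available but needs adequate group sizes.
- The ssGSEA index is comparable across samples only within a shared gene
  universe; it is not calibrated across datasets with different universes.
- NNLS deconvolution assumes the signature spans the mixture and linear
  additivity on the de-logged scale; collinear signatures are rejected
  rather than regularized.
- The logistic association reports a sentinel (NA) under perfect separation
  instead of a penalized fit.
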