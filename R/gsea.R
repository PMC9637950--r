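#' Rank genes by case-vs-control differential metric
#'
#' The default metric is the classic GSEA signal-to-noise ratio
#' `(mu_case - mu_ctrl) / (sd_case + sd_ctrl)` with each group's standard
#' deviation floored at `max(0.2 * |group mean|, 0.2)`, so near-constant
#' genes cannot dominate the ranking. `moderated_t` instead ranks by the
#' empirical-Bayes moderated t statistic from the differential-expression
#' module, which is better behaved for small groups. Positive metric =
#' higher expression in cases. Ties are broken deterministically by gene
#' symbol (ascending), after sorting by metric descending.
#'
#' @param ds an [expression_dataset()] with both groups present.
#' @param metric `"signal_to_noise"` or `"moderated_t"`.
#' @return A `RankedList`: list with `entries` (data.frame `gene`, `metric`,
#'   sorted) and `metric_name`.
#' @export
rank_genes <- function(ds, metric = c("signal_to_noise", "moderated_t")) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  metric <- match.arg(metric)
  grp <- ds$metadata$group
  if (sum(grp == "case") < 3 || sum(grp == "control") < 3)
    stop("each group needs >= 3 samples to rank genes")
  if (metric == "signal_to_noise") {
    m <- snr_metric(ds$values, grp == "case")
  } else {
    design <- build_design(ds$metadata, contrast = "case_vs_control")
    tab <- moderate_ebayes(fit_linear_models(ds, design))
    m <- stats::setNames(tab$t_mod, tab$gene)[ds$genes]
  }
  ord <- order(-m, names(m), method = "radix")
  structure(list(entries = data.frame(gene = names(m)[ord],
                                      metric = unname(m[ord]),
                                      stringsAsFactors = FALSE),
                 metric_name = metric),
            class = "RankedList")
}

# vectorized signal-to-noise with the classic variance floor
snr_metric <- function(values, is_case) {
  x1 <- values[, is_case, drop = FALSE]
  x0 <- values[, !is_case, drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  s1 <- apply(x1, 1, stats::sd); s0 <- apply(x0, 1, stats::sd)
  s1 <- pmax(s1, 0.2 * abs(m1), 0.2)
  s0 <- pmax(s0, 0.2 * abs(m0), 0.2)
  (m1 - m0) / (s1 + s0)
}

#' @export
print.RankedList <- function(x, ...) {
  cat(sprintf("RankedList (%s): %d genes, metric range [%.4g, %.4g]\n",
              x$metric_name, nrow(x$entries),
              min(x$entries$metric), max(x$entries$metric)))
  invisible(x)
}

# core running-sum computation on a prepared indicator; returns full curve.
# metric_w = |r|^weight at every position (descending rank order);
# in_set = logical indicator per position.
running_curve <- function(metric_w, in_set) {
  n <- length(in_set)
  n_hit <- sum(in_set)
  hit_inc <- ifelse(in_set, metric_w, 0)
  denom <- sum(hit_inc)
  cumsum(hit_inc) / denom - cumsum(!in_set) / (n - n_hit)
}

#' Weighted Kolmogorov-Smirnov running enrichment score
#'
#' Walks down the ranked list accumulating `P_hit(i) - P_miss(i)`, where
#' hits are weighted by `|metric|^weight` and misses uniformly by
#' `1/(N - N_hit)`. The enrichment score is the signed largest absolute
#' deviation of the running sum (earliest position on ties). Set genes
#' absent from the ranking are dropped first. If every set gene has zero
#' weighted metric, the statistic degenerates; the function falls back to
#' weight 0 with a warning.
#'
#' @param ranked a `RankedList` from [rank_genes()].
#' @param gene_set character vector of gene symbols.
#' @param weight exponent `p >= 0` on `|metric|`; 1 is the classic weighted
#'   statistic, 0 the unweighted Kolmogorov-Smirnov form.
#' @return A `RunningScore`: list with `es`, `curve`, `extremum_index`,
#'   `weight`, `in_set` (positional indicator used).
#' @export
running_es <- function(ranked, gene_set, weight = 1) {
  stopifnot(inherits(ranked, "RankedList"), weight >= 0)
  genes <- ranked$entries$gene
  in_set <- genes %in% gene_set
  if (!any(in_set)) stop("no gene of the set is present in the ranked list")
  if (all(in_set)) stop("gene set covers the whole ranked universe; ES undefined")
  metric_w <- abs(ranked$entries$metric)^weight
  if (sum(metric_w[in_set]) == 0) {
    warning("all |metric|^weight are zero for set genes; falling back to weight 0")
    weight <- 0
    metric_w <- rep(1, length(genes))
  }
  curve <- running_curve(metric_w, in_set)
  i <- which.max(abs(curve))       # earliest position on ties
  structure(list(es = curve[i], curve = curve, extremum_index = i,
                 weight = weight, in_set = in_set),
            class = "RunningScore")
}

#' Extract the leading-edge subset
#'
#' For a positive enrichment score, the set members ranked at or before the
#' running-sum peak; for a negative score (a downregulated set), the members
#' ranked at or after the trough — the genes that drive the enrichment
#' signal. Returned in ranking order.
#'
#' @param ranked the `RankedList` used to compute `rs`.
#' @param gene_set the gene set used to compute `rs`.
#' @param rs a `RunningScore` from [running_es()].
#' @return character vector of leading-edge genes (empty if `es == 0`).
#' @export
extract_leading_edge <- function(ranked, gene_set, rs) {
  stopifnot(inherits(ranked, "RankedList"), inherits(rs, "RunningScore"))
  genes <- ranked$entries$gene
  in_set <- genes %in% gene_set
  if (rs$es > 0) {
    genes[in_set & seq_along(genes) <= rs$extremum_index]
  } else if (rs$es < 0) {
    genes[in_set & seq_along(genes) >= rs$extremum_index]
  } else {
    character()
  }
}

#' Permutation significance for one gene set
#'
#' Two null schemes: `gene` permutes set membership over the ranked universe
#' (random sets of equal size on the fixed ranking); `phenotype` permutes
#' the case/control labels and re-ranks. The normalized enrichment score
#' divides the observed ES by the mean |null ES| of matching sign, and the
#' permutation p-value is `(1 + #{same-sign nulls with |ES*| >= |ES|}) /
#' (1 + #same-sign nulls)`.
#'
#' @param ds an [expression_dataset()].
#' @param gene_set character vector.
#' @param weight running-sum exponent, see [running_es()].
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed; results are reproducible given the seed.
#' @param scheme `"gene"` or `"phenotype"`.
#' @param metric ranking metric, see [rank_genes()].
#' @return list with `es`, `nes`, `p_value`, `leading_edge`, `n_perm`,
#'   `seed`, `scheme`, and `degenerate` (TRUE when no matching-sign nulls
#'   existed and `nes` is computed against epsilon).
#' @export
gsea_significance <- function(ds, gene_set, weight = 1, n_perm = 1000,
                              seed = 1, scheme = c("gene", "phenotype"),
                              metric = "signal_to_noise") {
  stopifnot(n_perm >= 100)
  scheme <- match.arg(scheme)
  ranked <- rank_genes(ds, metric)
  rs <- running_es(ranked, gene_set, weight)
  le <- extract_leading_edge(ranked, gene_set, rs)
  n <- nrow(ranked$entries)
  n_hit <- sum(rs$in_set)
  null_es <- with_seed(seed, {
    if (scheme == "gene") {
      metric_w <- abs(ranked$entries$metric)^rs$weight
      vapply(seq_len(n_perm), function(b) {
        idx <- sample.int(n, n_hit)
        ind <- logical(n); ind[idx] <- TRUE
        cv <- running_curve(metric_w, ind)
        cv[which.max(abs(cv))]
      }, 0)
    } else {
      grp <- ds$metadata$group
      vapply(seq_len(n_perm), function(b) {
        perm_case <- sample(grp) == "case"
        m <- snr_metric(ds$values, perm_case)
        ord <- order(-m, names(m), method = "radix")
        ind <- names(m)[ord] %in% gene_set
        cv <- running_curve(abs(m[ord])^rs$weight, ind)
        cv[which.max(abs(cv))]
      }, 0)
    }
  })
  same_sign <- if (rs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  degenerate <- length(same_sign) == 0
  if (degenerate) {
    warning("no matching-sign null enrichment scores; NES computed against epsilon")
    nes <- rs$es / .Machine$double.eps
    p <- 1
  } else {
    nes <- rs$es / mean(abs(same_sign))
    p <- (1 + sum(abs(same_sign) >= abs(rs$es))) / (1 + length(same_sign))
  }
  list(es = rs$es, nes = nes, p_value = p, leading_edge = le,
       n_perm = n_perm, seed = seed, scheme = scheme, degenerate = degenerate)
}

#' Run GSEA for every set in a collection
#'
#' Computes ES/NES/p per set against one dataset, attaches leading edges and
#' Benjamini-Hochberg FDR across the collection. Sets sharing no gene with
#' the dataset are skipped with a warning and listed in the `skipped`
#' attribute.
#'
#' @inheritParams gsea_significance
#' @param coll a [gene_set_collection()].
#' @return data.frame of class `GseaResultTable` with one row per scored
#'   set: `dataset_id`, `set_name`, `es`, `nes`, `p_value`, `fdr`,
#'   `leading_edge` (list column), `n_perm`, `seed`.
#' @export
run_gsea_collection <- function(ds, coll, weight = 1, n_perm = 1000, seed = 1,
                                scheme = c("gene", "phenotype"),
                                metric = "signal_to_noise") {
  stopifnot(inherits(coll, "GeneSetCollection"), length(coll$sets) > 0)
  scheme <- match.arg(scheme)
  present <- vapply(coll$sets, function(g) any(g %in% ds$genes), TRUE)
  if (any(!present))
    warning("skipping set(s) with no gene in dataset ", ds$dataset_id, ": ",
            paste(names(coll$sets)[!present], collapse = ", "))
  sets <- coll$sets[present]
  # derive one sub-seed per set so each set's null stream is independent
  # but the whole table is reproducible from `seed`
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max, length(sets)))
  rows <- lapply(seq_along(sets), function(i) {
    r <- gsea_significance(ds, sets[[i]], weight = weight, n_perm = n_perm,
                           seed = sub_seeds[i], scheme = scheme, metric = metric)
    data.frame(dataset_id = ds$dataset_id, set_name = names(sets)[i],
               es = r$es, nes = r$nes, p_value = r$p_value,
               leading_edge = I(list(r$leading_edge)),
               n_perm = n_perm, seed = seed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_value)
  out <- out[, c("dataset_id", "set_name", "es", "nes", "p_value", "fdr",
                 "leading_edge", "n_perm", "seed")]
  attr(out, "skipped") <- names(coll$sets)[!present]
  class(out) <- c("GseaResultTable", "data.frame")
  out
}

#' Write a GSEA result table as TSV (leading edges comma-joined)
#' @param res a `GseaResultTable`.
#' @param path output path.
#' @return invisible NULL.
#' @export
write_gsea_results <- function(res, path) {
  tab <- as.data.frame(res)
  tab$leading_edge <- vapply(tab$leading_edge, paste, "", collapse = ",")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
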