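#' Pool cross-dataset leading edges into a core gene set
#'
#' A gene counts as "leading in dataset d" when it appears in the leading
#' edge of at least one gene set whose GSEA result in d passes the direction
#' filter (for `"down"`, ES < 0) and, when `fdr_max` is given, has
#' `fdr <= fdr_max`. Genes leading in at least `min_datasets` distinct
#' datasets form the core set — the cross-dataset consensus analogous to
#' selecting leading genes found in at least half of the datasets.
#'
#' @param results one `GseaResultTable` (rows from several datasets) or a
#'   list of them; they are row-bound.
#' @param min_datasets minimum number of distinct supporting datasets (>= 1).
#' @param require_direction `"down"`, `"up"`, or `"any"`; default `"down"`
#'   (pooling leading edges of downregulated sets).
#' @param fdr_max optional FDR ceiling on the contributing GSEA results;
#'   `NULL` disables the significance filter. Default 0.05.
#' @return A `CoreGeneSet`: list with `genes` (sorted), `support`
#'   (named list gene -> dataset ids), `min_datasets`.
#' @export
pool_core_genes <- function(results, min_datasets = 2,
                            require_direction = c("down", "up", "any"),
                            fdr_max = 0.05) {
  require_direction <- match.arg(require_direction)
  if (min_datasets < 1) stop("min_datasets must be >= 1")
  if (is.data.frame(results)) results <- list(results)
  tab <- do.call(rbind, lapply(results, as.data.frame))
  n_ds <- length(unique(tab$dataset_id))
  if (n_ds < min_datasets)
    stop("results cover ", n_ds, " dataset(s) but min_datasets = ", min_datasets)
  keep <- switch(require_direction,
                 down = tab$es < 0, up = tab$es > 0,
                 any = rep(TRUE, nrow(tab)))
  if (!is.null(fdr_max)) keep <- keep & tab$fdr <= fdr_max
  tab <- tab[keep, , drop = FALSE]
  support <- list()
  for (i in seq_len(nrow(tab))) {
    for (g in tab$leading_edge[[i]]) {
      support[[g]] <- union(support[[g]], tab$dataset_id[i])
    }
  }
  genes <- sort(names(support)[vapply(support, length, 0L) >= min_datasets])
  structure(list(genes = genes, support = support[genes],
                 min_datasets = min_datasets),
            class = "CoreGeneSet")
}

#' @export
print.CoreGeneSet <- function(x, ...) {
  cat(sprintf("CoreGeneSet: %d genes supported by >= %d datasets\n",
              length(x$genes), x$min_datasets))
  if (length(x$genes)) cat("  ", paste(utils::head(x$genes, 12), collapse = ", "),
                           if (length(x$genes) > 12) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Export a core gene set as GMT plus a support TSV
#' @param core a `CoreGeneSet`.
#' @param gmt_path,support_path output paths.
#' @param set_name name for the GMT line.
#' @return invisible NULL.
#' @export
write_core_gene_set <- function(core, gmt_path, support_path,
                                set_name = "core_glycolysis") {
  write_gmt(gene_set_collection(stats::setNames(list(core$genes), set_name),
                                source = "pool_core_genes"), gmt_path)
  sup <- data.frame(gene = core$genes,
                    n_datasets = vapply(core$support, length, 0L),
                    datasets = vapply(core$support, paste, "", collapse = ","),
                    stringsAsFactors = FALSE)
  utils::write.table(sup, support_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

# single-sample enrichment score for one expression vector.
# v: named expression values; in_set determined by symbol membership.
# Integrated (summed) weighted ECDF difference over the descending ranking,
# with rank values (1 = lowest expression) raised to alpha as hit weights.
ssgsea_es_single <- function(values, genes, set_membership, alpha) {
  n <- length(values)
  ord <- order(-values, genes, method = "radix")  # value desc, symbol asc
  in_set <- set_membership[ord]
  v <- (n:1)^alpha                 # rank-from-bottom weight at each position
  hit_inc <- ifelse(in_set, v, 0)
  n_in <- sum(in_set)
  p_in <- cumsum(hit_inc) / sum(hit_inc)
  p_out <- cumsum(!in_set) / (n - n_in)
  sum(p_in - p_out)
}

#' Single-sample GSEA enrichment scores
#'
#' For each sample, genes are ranked by expression (descending; ties broken
#' by gene symbol so the score is deterministic), and the enrichment score
#' is the integrated difference between the rank-weighted in-set ECDF
#' (weights = within-sample rank from the bottom, raised to `alpha`) and the
#' uniform out-of-set ECDF — the integrated-sum ssGSEA statistic, not the
#' running-sum extremum. Scores depend only on within-sample ranks, so any
#' monotone transform of one sample's values leaves its score unchanged, and
#' samples are scored independently unless `normalize = TRUE`, which divides
#' all scores by the max-min range across samples.
#'
#' @param ds an [expression_dataset()].
#' @param gene_set character vector; at least one gene must be present in
#'   `ds` and at least one absent.
#' @param alpha rank-weighting exponent (>= 0); 0.25 is the common default.
#' @param normalize divide scores by their cross-sample range.
#' @param score_name label for the returned scores.
#' @return A [sample_score_vector()].
#' @export
ssgsea_score <- function(ds, gene_set, alpha = 0.25, normalize = FALSE,
                         score_name = "ssgsea_es") {
  stopifnot(inherits(ds, "ExpressionDataset"), alpha >= 0)
  membership <- ds$genes %in% gene_set
  if (!any(membership)) stop("no gene of the set is present in the dataset")
  if (all(membership)) stop("gene set covers every dataset gene; ES undefined")
  if (normalize && length(ds$samples) < 2)
    stop("normalize = TRUE needs >= 2 samples (range undefined)")
  scores <- vapply(seq_along(ds$samples), function(j)
    ssgsea_es_single(ds$values[, j], ds$genes, membership, alpha), 0)
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng == 0) stop("all scores identical; range normalization undefined")
    scores <- scores / rng
  }
  sample_score_vector(ds$samples, scores, score_name, alpha = alpha,
                      normalized = normalize)
}

#' Per-sample glycolysis index
#'
#' The glycolysis index of a sample is its ssGSEA enrichment score for the
#' pooled core glycolysis gene set: a rank-based summary of how highly the
#' core genes are expressed within the sample.
#'
#' @param ds an [expression_dataset()].
#' @param core a `CoreGeneSet` from [pool_core_genes()] (or a plain
#'   character vector of genes).
#' @param alpha rank-weighting exponent, see [ssgsea_score()].
#' @param normalize see [ssgsea_score()].
#' @return A [sample_score_vector()] named `glycolysis_index`.
#' @export
glycolysis_index <- function(ds, core, alpha = 0.25, normalize = FALSE) {
  genes <- if (inherits(core, "CoreGeneSet")) core$genes else as.character(core)
  ssgsea_score(ds, genes, alpha = alpha, normalize = normalize,
               score_name = "glycolysis_index")
}

#' Median split of sample scores within each brain region
#'
#' Within each region, samples at or below the regional median score are
#' labelled `"low"`, the rest `"high"`. Regions are split independently, so
#' differing regional score levels do not leak across regions. A
#' single-sample region is labelled `"low"` with a warning.
#'
#' @param scores a [sample_score_vector()].
#' @param meta metadata data.frame with `sample_id` and `region` covering
#'   every scored sample.
#' @return named character vector (`"low"`/`"high"`) in the order of
#'   `scores$sample_ids`.
#' @export
median_split_by_region <- function(scores, meta) {
  stopifnot(inherits(scores, "SampleScoreVector"))
  idx <- match(scores$sample_ids, meta$sample_id)
  if (anyNA(idx)) stop("sample(s) missing from metadata: ",
                       paste(scores$sample_ids[is.na(idx)], collapse = ", "))
  region <- meta$region[idx]
  out <- character(length(scores$scores))
  for (r in unique(region)) {
    sel <- region == r
    if (sum(sel) == 1) {
      warning("region ", r, " has a single sample; labelled 'low'")
      out[sel] <- "low"
    } else {
      med <- stats::median(scores$scores[sel])
      out[sel] <- ifelse(scores$scores[sel] <= med, "low", "high")
    }
  }
  stats::setNames(out, scores$sample_ids)
}

#' Export index scores with split labels as TSV
#' @param scores a [sample_score_vector()].
#' @param meta sample metadata (`sample_id`, `region`, `group`).
#' @param labels output of [median_split_by_region()].
#' @param path output path.
#' @return invisible NULL.
#' @export
write_index_table <- function(scores, meta, labels, path) {
  idx <- match(scores$sample_ids, meta$sample_id)
  tab <- data.frame(sample_id = scores$sample_ids,
                    region = meta$region[idx], group = meta$group[idx],
                    index = scores$scores,
                    split_label = labels[scores$sample_ids],
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
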