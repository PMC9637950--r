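#' Per-dataset Spearman co-expression between two gene panels
#'
#' Computes the Spearman correlation, t-approximation p-value and
#' Benjamini-Hochberg FDR for every cross pair (one gene from each panel,
#' identical genes skipped) present in the dataset. Constant genes are
#' untestable: their pairs are flagged and excluded from the FDR family. The
#' FDR family is all pairs tested within this dataset.
#'
#' @param ds an [expression_dataset()].
#' @param genes_a,genes_b character vectors (e.g. glycolysis genes and cell
#'   marker genes).
#' @return data.frame of class `CoexprEdgeTable`: `dataset_id`, `gene_a`,
#'   `gene_b`, `rho`, `p_value`, `fdr`, `significant` (fdr < 0.05, strict),
#'   `testable`.
#' @export
coexpr_per_dataset <- function(ds, genes_a, genes_b) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  ga <- intersect(unique(genes_a), ds$genes)
  gb <- intersect(unique(genes_b), ds$genes)
  if (!length(ga) || !length(gb))
    stop("a gene panel shares no genes with dataset ", ds$dataset_id)
  n <- length(ds$samples)
  ra <- apply(ds$values[ga, , drop = FALSE], 1, rank)   # samples x genes
  rb <- apply(ds$values[gb, , drop = FALSE], 1, rank)
  const_a <- apply(ds$values[ga, , drop = FALSE], 1, function(v) length(unique(v)) == 1)
  const_b <- apply(ds$values[gb, , drop = FALSE], 1, function(v) length(unique(v)) == 1)
  rho_mat <- suppressWarnings(stats::cor(ra, rb))       # Pearson on ranks
  pairs <- expand.grid(gene_a = ga, gene_b = gb, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  pairs <- pairs[pairs$gene_a != pairs$gene_b, , drop = FALSE]
  pairs$rho <- rho_mat[cbind(pairs$gene_a, pairs$gene_b)]
  pairs$testable <- !(const_a[pairs$gene_a] | const_b[pairs$gene_b])
  pairs$rho[!pairs$testable] <- NA_real_
  tstat <- pairs$rho * sqrt((n - 2) / pmax(1 - pairs$rho^2, .Machine$double.eps))
  pairs$p_value <- ifelse(abs(pairs$rho) >= 1, 0, 2 * stats::pt(-abs(tstat), df = n - 2))
  pairs$fdr <- NA_real_
  pairs$fdr[pairs$testable] <- bh_adjust(pairs$p_value[pairs$testable])
  pairs$significant <- !is.na(pairs$fdr) & pairs$fdr < 0.05
  out <- cbind(dataset_id = ds$dataset_id, pairs)
  rownames(out) <- NULL
  class(out) <- c("CoexprEdgeTable", "data.frame")
  out
}

#' Consensus co-expression / PPI network
#'
#' A gene pair carries five evidence channels: significance (FDR < 0.05) in
#' each of the (typically four) dataset co-expression tables, plus presence
#' in the high-confidence PPI table. A pair becomes a consensus edge when at
#' least `min_support` channels support it and (when
#' `require_sign_consistency`) the correlation signs agree across all
#' datasets where the pair is significant; the edge sign is that shared
#' sign. PPI support carries no sign, so a pair needs dataset evidence to
#' have a defined sign. The result is independent of dataset order.
#'
#' @param tables list of `CoexprEdgeTable`, one per dataset.
#' @param ppi a [ppi_table()] of high-confidence interactions (already
#'   filtered to the confidence cutoff).
#' @param min_support minimum number of supporting channels (default 4 of 5).
#' @param require_sign_consistency drop pairs whose significant datasets
#'   disagree in sign (default TRUE).
#' @param roles optional named character vector gene -> role (e.g.
#'   `"glycolysis"`, `"marker:microglia"`) stored on the nodes.
#' @return A `ConsensusNetwork`: list with `edges` (data.frame `gene_a`,
#'   `gene_b`, `sign`, `support_count`, one `sig_<dataset>` flag column per
#'   dataset, `ppi` flag) and `nodes` (data.frame `name`, `role`).
#' @export
consensus_network <- function(tables, ppi, min_support = 4,
                              require_sign_consistency = TRUE, roles = NULL) {
  stopifnot(length(tables) >= 1)
  if (min_support < 1) stop("min_support must be >= 1")
  if (min_support > length(tables) + 1)
    stop("min_support exceeds the number of evidence channels (",
         length(tables) + 1, ")")
  ds_ids <- sort(vapply(tables, function(t) t$dataset_id[1], ""))
  if (anyDuplicated(ds_ids)) stop("duplicate dataset ids among tables")
  tables <- tables[order(vapply(tables, function(t) t$dataset_id[1], ""))]
  # canonical unordered pair key
  all_tab <- do.call(rbind, lapply(tables, function(t)
    data.frame(dataset_id = t$dataset_id,
               a = pmin(t$gene_a, t$gene_b), b = pmax(t$gene_a, t$gene_b),
               rho = t$rho, significant = t$significant,
               stringsAsFactors = FALSE)))
  all_tab$key <- paste(all_tab$a, all_tab$b, sep = "\r")
  ppi_keys <- if (nrow(ppi)) paste(pmin(ppi$gene_a, ppi$gene_b),
                                   pmax(ppi$gene_a, ppi$gene_b), sep = "\r")
              else character()
  keys <- sort(unique(all_tab$key))
  rows <- lapply(keys, function(k) {
    sub <- all_tab[all_tab$key == k, , drop = FALSE]
    sig_flags <- stats::setNames(rep(FALSE, length(ds_ids)), ds_ids)
    sig_flags[sub$dataset_id[sub$significant]] <- TRUE
    in_ppi <- k %in% ppi_keys
    support <- sum(sig_flags) + in_ppi
    if (support < min_support) return(NULL)
    sig_rho <- sub$rho[sub$significant]
    if (length(sig_rho) == 0) return(NULL)            # sign undefined (PPI-only)
    signs <- unique(sign(sig_rho))
    if (require_sign_consistency && length(signs) > 1) return(NULL)
    edge_sign <- if (length(signs) == 1) signs else sign(stats::median(sig_rho))
    out <- data.frame(gene_a = sub$a[1], gene_b = sub$b[1],
                      sign = as.integer(edge_sign),
                      support_count = as.integer(support),
                      stringsAsFactors = FALSE)
    for (d in ds_ids) out[[paste0("sig_", d)]] <- unname(sig_flags[d])
    out$ppi <- in_ppi
    out
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(), gene_b = character(), sign = integer(),
               support_count = integer(), ppi = logical())
  node_names <- sort(unique(c(edges$gene_a, edges$gene_b)))
  nodes <- data.frame(name = node_names,
                      role = if (is.null(roles)) rep(NA_character_, length(node_names))
                             else unname(roles[node_names]),
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = nodes, min_support = min_support,
                 dataset_ids = ds_ids,
                 require_sign_consistency = require_sign_consistency),
            class = "ConsensusNetwork")
}

#' @export
print.ConsensusNetwork <- function(x, ...) {
  cat(sprintf("ConsensusNetwork: %d edges over %d nodes (min_support = %d of %d channels)\n",
              nrow(x$edges), nrow(x$nodes), x$min_support, length(x$dataset_ids) + 1))
  invisible(x)
}
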