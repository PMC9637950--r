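#' Hypergeometric over-representation analysis
#'
#' Tests each annotation term for enrichment of the query list within an
#' explicit background universe (for the cross-dataset analyses, the genes
#' measured in all datasets). Every term is first restricted to the
#' background; query genes outside the background are dropped with a
#' warning. One-sided enrichment p-values `P(X >= k)` with
#' `X ~ Hypergeometric(N, K, n)`, Benjamini-Hochberg adjusted across all
#' tested terms. Terms with no background gene are skipped.
#'
#' @param query character vector of gene symbols.
#' @param annotation a [gene_set_collection()] of terms.
#' @param background character vector: the gene universe.
#' @return data.frame of class `OraResultTable`: `term`, `k` (query hits),
#'   `K` (term size in background), `n` (query size in background),
#'   `N` (background size), `p_value`, `fdr`, `hit_genes` (comma-joined),
#'   sorted by p-value.
#' @export
ora_enrich <- function(query, annotation, background) {
  stopifnot(inherits(annotation, "GeneSetCollection"), length(background) > 0)
  background <- unique(as.character(background))
  query <- unique(as.character(query))
  outside <- setdiff(query, background)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the background dropped")
    query <- intersect(query, background)
  }
  if (!length(query)) stop("query is empty after restriction to the background")
  n <- length(query)
  N <- length(background)
  rows <- lapply(names(annotation$sets), function(term) {
    term_genes <- intersect(annotation$sets[[term]], background)
    K <- length(term_genes)
    if (K == 0) return(NULL)
    hits <- intersect(query, term_genes)
    k <- length(hits)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p_value = p,
               hit_genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(structure(data.frame(term = character(), k = integer(), K = integer(),
                                n = integer(), N = integer(), p_value = numeric(),
                                fdr = numeric(), hit_genes = character()),
                     class = c("OraResultTable", "data.frame")))
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$term), c("term", "k", "K", "n", "N",
                                             "p_value", "fdr", "hit_genes")]
  rownames(out) <- NULL
  class(out) <- c("OraResultTable", "data.frame")
  out
}
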