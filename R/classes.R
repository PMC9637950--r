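#' Construct an expression dataset
#'
#' Binds a genes x samples matrix of log2-scale expression values to
#' per-sample metadata. All downstream stages (GSEA, ssGSEA scoring,
#' differential expression, co-expression) consume this container.
#'
#' Values are assumed to be on the log2 scale: the differential-expression
#' stage interprets coefficients as log2 fold changes. Rank-based stages
#' (GSEA, ssGSEA, Spearman correlation) are invariant to any monotone
#' transform, so the scale contract only matters for `diff_expression()` and
#' `nnls_deconvolve()` (which de-logs with `2^x - 1`).
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids). No missing values allowed.
#' @param metadata data.frame with columns `sample_id`, `group`
#'   (`"control"`/`"case"`), `region`, `age` (non-negative years), `sex`
#'   (`"F"`/`"M"`). One row per sample column; order may differ, rows are
#'   aligned to the matrix columns by `sample_id`.
#' @param dataset_id character scalar identifying the dataset.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `dataset_id`, `genes`, `samples`, `values`, `metadata`.
#' @export
expression_dataset <- function(values, metadata, dataset_id) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must have gene rownames and sample colnames")
  if (anyNA(values))
    stop("expression matrix contains missing values; impute or filter before loading")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbols in expression matrix; collapse them first ",
         "(read_expression_dataset() collapses duplicates by row median)")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in expression matrix")
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  req <- c("sample_id", "group", "region", "age", "sex")
  miss <- setdiff(req, names(metadata))
  if (length(miss))
    stop("metadata is missing required column(s): ", paste(miss, collapse = ", "))
  extra_meta <- setdiff(metadata$sample_id, colnames(values))
  extra_expr <- setdiff(colnames(values), metadata$sample_id)
  if (length(extra_expr) || length(extra_meta))
    stop("sample alignment error; in matrix but not metadata: [",
         paste(extra_expr, collapse = ", "), "]; in metadata but not matrix: [",
         paste(extra_meta, collapse = ", "), "]")
  if (anyDuplicated(metadata$sample_id)) stop("duplicate sample ids in metadata")
  metadata <- metadata[match(colnames(values), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  if (!all(metadata$group %in% c("control", "case")))
    stop("metadata group must be 'control' or 'case'")
  if (!all(metadata$sex %in% c("F", "M")))
    stop("metadata sex must be 'F' or 'M'")
  if (!is.numeric(metadata$age) || any(metadata$age < 0))
    stop("metadata age must be non-negative numeric")
  structure(
    list(dataset_id = as.character(dataset_id),
         genes = rownames(values),
         samples = colnames(values),
         values = values,
         metadata = metadata),
    class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset '%s': %d genes x %d samples (%d case / %d control)\n",
              x$dataset_id, length(x$genes), length(x$samples),
              sum(x$metadata$group == "case"), sum(x$metadata$group == "control")))
  cat(sprintf("  regions: %s\n", paste(unique(x$metadata$region), collapse = ", ")))
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)

#' Construct a gene set collection
#'
#' @param sets named list of character vectors of gene symbols.
#' @param source character scalar describing provenance (e.g. file path).
#' @return Object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, source = "") {
  if (length(sets) && is.null(names(sets))) stop("gene sets must be named")
  if (anyDuplicated(names(sets))) stop("duplicate gene set names")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0)) stop("every gene set must be non-empty")
  structure(list(sets = sets, source = as.character(source)),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets (sizes %s)\n", length(x$sets),
              if (length(x$sets)) paste(range(lengths(x$sets)), collapse = "-") else "-"))
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' Construct a protein-protein interaction table
#'
#' Unordered duplicate pairs are collapsed keeping the maximum score;
#' self-loops are rejected. Scores follow the STRING convention rescaled to
#' `[0, 1]` (a STRING combined score of 700 corresponds to 0.7).
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `score`.
#' @return Object of class `PpiTable` (a data.frame with canonicalised,
#'   deduplicated edges).
#' @export
ppi_table <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0)
    return(structure(data.frame(gene_a = character(), gene_b = character(),
                                score = numeric()), class = c("PpiTable", "data.frame")))
  stopifnot(all(c("gene_a", "gene_b", "score") %in% names(edges)))
  if (any(edges$score < 0 | edges$score > 1))
    stop("PPI scores must lie in [0, 1]")
  if (any(edges$gene_a == edges$gene_b))
    stop("self-loop in PPI table: ", edges$gene_a[edges$gene_a == edges$gene_b][1])
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  key <- paste(a, b, sep = "\r")
  score <- tapply(edges$score, key, max)
  keys <- names(score)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(gene_a = vapply(parts, `[`, "", 1),
                    gene_b = vapply(parts, `[`, "", 2),
                    score = as.numeric(score), stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("PpiTable", "data.frame"))
}

#' Construct a cell-type signature matrix
#'
#' Reference expression profiles on the linear (not log) scale, used by
#' `nnls_deconvolve()` and by `generate_mixture_samples()`.
#'
#' @param values non-negative numeric matrix, genes x cell types, with
#'   rownames (genes) and colnames (cell types).
#' @return Object of class `SignatureMatrix`.
#' @export
signature_matrix <- function(values) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("signature matrix must have gene rownames and cell-type colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate genes in signature matrix")
  if (anyDuplicated(colnames(values))) stop("duplicate cell types in signature matrix")
  if (any(values < 0)) stop("signature matrix values must be non-negative")
  structure(list(genes = rownames(values), cell_types = colnames(values),
                 values = values), class = "SignatureMatrix")
}

#' @export
print.SignatureMatrix <- function(x, ...) {
  cat(sprintf("SignatureMatrix: %d genes x %d cell types (%s)\n",
              length(x$genes), length(x$cell_types),
              paste(x$cell_types, collapse = ", ")))
  invisible(x)
}

#' Per-sample score vector (ssGSEA enrichment scores)
#'
#' @param sample_ids character vector of sample ids.
#' @param scores numeric vector, one finite score per sample.
#' @param score_name name of the score (e.g. `"glycolysis_index"`).
#' @param alpha rank-weighting exponent used to compute the scores.
#' @param normalized logical; whether scores were divided by their range.
#' @return Object of class `SampleScoreVector`.
#' @export
sample_score_vector <- function(sample_ids, scores, score_name,
                                alpha = 0.25, normalized = FALSE) {
  stopifnot(length(sample_ids) == length(scores))
  if (!all(is.finite(scores))) stop("scores must be finite")
  structure(list(sample_ids = as.character(sample_ids),
                 scores = as.numeric(scores),
                 score_name = as.character(score_name),
                 alpha = alpha, normalized = isTRUE(normalized)),
            class = "SampleScoreVector")
}

#' @export
print.SampleScoreVector <- function(x, ...) {
  cat(sprintf("SampleScoreVector '%s': %d samples, range [%.4g, %.4g]%s\n",
              x$score_name, length(x$scores), min(x$scores), max(x$scores),
              if (x$normalized) " (range-normalized)" else ""))
  invisible(x)
}

#' @export
as.numeric.SampleScoreVector <- function(x, ...) {
  stats::setNames(x$scores, x$sample_ids)
}

# internal: deterministic RNG scoping -- run expr with a local seed without
# disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
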