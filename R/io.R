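#' Parse a GMT gene-set file
#'
#' Reads the tab-separated MSigDB GMT dialect: one set per line,
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are dropped keeping first occurrence; the description field is
#' discarded (the file path is kept as the collection `source`).
#'
#' @param path path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
parse_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(gene_set_collection(list(), source = path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed GMT line ", which(nf < 3)[1], ": fewer than 3 tab-separated fields")
  nm <- vapply(fields, `[`, "", 1)
  if (anyDuplicated(nm))
    stop("duplicate gene set name in GMT: ", nm[duplicated(nm)][1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  gene_set_collection(sets, source = path)
}

#' Write a gene set collection to GMT
#'
#' @param coll a [gene_set_collection()].
#' @param path output file path.
#' @param descriptions optional character vector of per-set descriptions
#'   (defaults to the set names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(coll, path, descriptions = NULL) {
  stopifnot(inherits(coll, "GeneSetCollection"))
  if (is.null(descriptions)) descriptions <- names(coll$sets)
  lines <- mapply(function(nm, desc, genes)
    paste(c(nm, desc, genes), collapse = "\t"),
    names(coll$sets), descriptions, coll$sets)
  writeLines(as.character(lines), path)
  invisible(path)
}

#' Read an expression matrix plus sample metadata
#'
#' The expression TSV has gene symbols in the first column and sample ids as
#' the header; the metadata TSV has columns `sample_id`, `group`, `region`,
#' `age`, `sex`. Samples are aligned by id. Duplicate gene symbols are
#' collapsed by per-row median, the convention used for probe-to-symbol
#' summarisation of microarray data.
#'
#' @param expr_path path to the expression TSV.
#' @param meta_path path to the metadata TSV.
#' @param dataset_id identifier for the resulting dataset.
#' @return An [expression_dataset()].
#' @export
read_expression_dataset <- function(expr_path, meta_path, dataset_id) {
  tab <- utils::read.delim(expr_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression TSV needs a gene column plus >=1 sample")
  genes <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric expression cell in ", expr_path)
  storage.mode(mat) <- "double"
  if (anyDuplicated(genes)) {
    # collapse duplicate symbols by per-row median
    mat <- do.call(rbind, lapply(split(seq_along(genes), genes), function(idx) {
      if (length(idx) == 1) mat[idx, , drop = TRUE]
      else apply(mat[idx, , drop = FALSE], 2, stats::median)
    }))
    # split() sorts by name; restore first-occurrence order
    first_order <- genes[!duplicated(genes)]
    mat <- mat[first_order, , drop = FALSE]
    rownames(mat) <- first_order
  } else {
    rownames(mat) <- genes
  }
  meta <- utils::read.delim(meta_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  meta$sample_id <- as.character(meta$sample_id)
  expression_dataset(mat, meta, dataset_id)
}

#' Write an expression dataset as TSV pair
#'
#' @param ds an [expression_dataset()].
#' @param expr_path,meta_path output paths.
#' @return invisible NULL.
#' @export
write_expression_dataset <- function(ds, expr_path, meta_path) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  tab <- data.frame(gene = ds$genes, ds$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$metadata, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Read a PPI edge table, keeping high-confidence edges
#'
#' Only edges with `score > min_score` (strictly greater) are retained,
#' following the high-confidence convention for STRING interactions
#' (combined score > 0.7 on the 0-1 scale; STRING's integer 700 = 0.7).
#'
#' @param path TSV with columns `gene_a`, `gene_b`, `score`.
#' @param min_score confidence cutoff in `[0, 1]`; default 0.7.
#' @return A [ppi_table()].
#' @export
read_ppi_table <- function(path, min_score = 0.7) {
  stopifnot(min_score >= 0, min_score <= 1)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0) return(ppi_table(tab[, c("gene_a", "gene_b", "score")]))
  stopifnot(all(c("gene_a", "gene_b", "score") %in% names(tab)))
  if (any(tab$score < 0 | tab$score > 1))
    stop("PPI score outside [0, 1] in ", path)
  pt <- ppi_table(tab[, c("gene_a", "gene_b", "score")])
  out <- pt[pt$score > min_score, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("PpiTable", "data.frame"))
}

#' Write a signature matrix as TSV
#' @param sig a [signature_matrix()].
#' @param path output path.
#' @return invisible NULL.
#' @export
write_signature_matrix <- function(sig, path) {
  stopifnot(inherits(sig, "SignatureMatrix"))
  tab <- data.frame(gene = sig$genes, sig$values, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read a signature matrix from TSV
#' @param path TSV with gene symbols in the first column, cell types as header.
#' @return A [signature_matrix()].
#' @export
read_signature_matrix <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(tab[[1]])
  signature_matrix(mat)
}

#' Export a consensus network
#'
#' `sif` writes Cytoscape simple-interaction lines with interaction label
#' `pos`/`neg` by edge sign; `tsv` writes the full edge table (sign,
#' support count, per-evidence flags) and round-trips exactly through
#' [read_network_tsv()]; `graphml` writes GraphML for graph tools.
#'
#' @param net a `ConsensusNetwork` from [consensus_network()].
#' @param path output file path.
#' @param format one of `"sif"`, `"graphml"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "sif", "graphml")) {
  stopifnot(inherits(net, "ConsensusNetwork"))
  format <- match.arg(format)
  ed <- net$edges
  if (format == "sif") {
    lines <- if (nrow(ed)) paste(ed$gene_a,
                                 ifelse(ed$sign > 0, "pos", "neg"),
                                 ed$gene_b) else character()
    writeLines(lines, path)
  } else if (format == "tsv") {
    utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      if (nrow(ed)) ed[, c("gene_a", "gene_b")] else
        data.frame(from = character(), to = character()),
      directed = FALSE,
      vertices = if (nrow(net$nodes)) net$nodes else NULL)
    if (nrow(ed)) {
      igraph::E(g)$sign <- ed$sign
      igraph::E(g)$support_count <- ed$support_count
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read back a network edge table written by `write_network(format = "tsv")`
#' @param path TSV path.
#' @return data.frame of edges.
#' @export
read_network_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
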