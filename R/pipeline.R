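#' Load and validate a pipeline configuration
#'
#' The configuration is a YAML file with the input paths and stage
#' parameters; see [pipeline_config()] for the fields and defaults.
#'
#' @param path YAML file.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$base_dir <- dirname(normalizePath(path))
  do.call(pipeline_config, raw)
}

#' Assemble a pipeline configuration
#'
#' @param datasets named list: region/dataset id -> list(expr =, meta =) TSV
#'   paths.
#' @param gene_sets path to the glycolysis GMT.
#' @param markers path to the cell-marker GMT.
#' @param ppi path to the PPI TSV.
#' @param signature path to the signature TSV.
#' @param out_dir output directory.
#' @param gsea list: `weight`, `n_perm`, `seed`, `scheme`.
#' @param pooling list: `min_datasets`, `direction`, `fdr_max`.
#' @param ssgsea list: `alpha`, `normalize`.
#' @param de list: `fdr_max`, `lfc_min`, `age_df`.
#' @param network list: `min_support`, `sign_consistency`, `ppi_min_score`.
#' @param base_dir optional directory against which relative paths resolve.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(datasets, gene_sets, markers, ppi, signature,
                            out_dir,
                            gsea = list(), pooling = list(), ssgsea = list(),
                            de = list(), network = list(), base_dir = NULL) {
  merge_defaults <- function(given, defaults) {
    extra <- setdiff(names(given), names(defaults))
    if (length(extra)) stop("unknown config field(s): ", paste(extra, collapse = ", "))
    utils::modifyList(defaults, given)
  }
  gsea <- merge_defaults(gsea, list(weight = 1, n_perm = 1000, seed = 1,
                                    scheme = "gene"))
  pooling <- merge_defaults(pooling, list(min_datasets = 2, direction = "down",
                                          fdr_max = 0.05))
  ssgsea <- merge_defaults(ssgsea, list(alpha = 0.25, normalize = FALSE))
  de <- merge_defaults(de, list(fdr_max = 0.05, lfc_min = 0.5, age_df = 1))
  network <- merge_defaults(network, list(min_support = 4,
                                          sign_consistency = TRUE,
                                          ppi_min_score = 0.7))
  resolve <- function(p) {
    if (!is.null(base_dir) && !grepl("^(/|[A-Za-z]:)", p)) file.path(base_dir, p) else p
  }
  datasets <- lapply(datasets, function(d) list(expr = resolve(d$expr),
                                                meta = resolve(d$meta)))
  cfg <- list(datasets = datasets, gene_sets = resolve(gene_sets),
              markers = resolve(markers), ppi = resolve(ppi),
              signature = resolve(signature), out_dir = out_dir,
              gsea = gsea, pooling = pooling, ssgsea = ssgsea, de = de,
              network = network)
  validate_pipeline_config(cfg)
  structure(cfg, class = "PipelineConfig")
}

validate_pipeline_config <- function(cfg) {
  paths <- c(unlist(lapply(cfg$datasets, unlist)), cfg$gene_sets, cfg$markers,
             cfg$ppi, cfg$signature)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("config references missing file(s): ",
                            paste(missing, collapse = ", "))
  if (cfg$network$min_support > length(cfg$datasets) + 1)
    stop("min_support (", cfg$network$min_support,
         ") exceeds the number of evidence channels (",
         length(cfg$datasets) + 1, ")")
  if (cfg$de$fdr_max <= 0 || cfg$de$lfc_min <= 0)
    stop("DE thresholds must be positive")
  if (cfg$pooling$min_datasets < 1) stop("min_datasets must be >= 1")
  invisible(cfg)
}

#' Run the full glycolysis-index analysis
#'
#' Executes every stage in order: per-dataset GSEA over the gene-set
#' collection, pooling of leading edges into the core gene set, per-sample
#' glycolysis index plus per-region median split, case-vs-control and
#' high-vs-low-index differential expression on the combined dataset with
#' region/age/sex covariates, DEG overlap, over-representation analysis of
#' the overlap against the gene-set collection (background = genes measured
#' in all datasets), marker scoring + NNLS deconvolution + group/index
#' associations, and the consensus co-expression/PPI network. Every
#' intermediate table is written under `out_dir`, along with a manifest
#' (stage outputs, MD5 hashes, parameters). Identical configuration and
#' seed give byte-identical outputs.
#'
#' @param cfg a `PipelineConfig`.
#' @param quiet suppress progress messages.
#' @return list with every stage result plus `manifest`, invisibly.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[glycoindex] ", ...)
  outputs <- character()
  emit <- function(name) outputs[[length(outputs) + 1]] <<- file.path(cfg$out_dir, name)

  say("loading inputs")
  datasets <- lapply(names(cfg$datasets), function(id)
    read_expression_dataset(cfg$datasets[[id]]$expr, cfg$datasets[[id]]$meta, id))
  names(datasets) <- names(cfg$datasets)
  coll <- parse_gmt(cfg$gene_sets)
  markers <- parse_gmt(cfg$markers)
  ppi <- read_ppi_table(cfg$ppi, min_score = cfg$network$ppi_min_score)
  sig <- read_signature_matrix(cfg$signature)

  say("stage 1/8: GSEA per dataset")
  gsea_res <- lapply(datasets, function(ds)
    run_gsea_collection(ds, coll, weight = cfg$gsea$weight,
                        n_perm = cfg$gsea$n_perm, seed = cfg$gsea$seed,
                        scheme = cfg$gsea$scheme))
  for (id in names(gsea_res))
    write_gsea_results(gsea_res[[id]], file.path(cfg$out_dir,
                                                 paste0("gsea_", id, ".tsv")))
  for (id in names(gsea_res)) emit(paste0("gsea_", id, ".tsv"))

  say("stage 2/8: pooling core genes")
  core <- pool_core_genes(gsea_res, min_datasets = cfg$pooling$min_datasets,
                          require_direction = cfg$pooling$direction,
                          fdr_max = cfg$pooling$fdr_max)
  write_core_gene_set(core, file.path(cfg$out_dir, "core_genes.gmt"),
                      file.path(cfg$out_dir, "core_support.tsv"))
  emit("core_genes.gmt"); emit("core_support.tsv")
  if (!length(core$genes))
    stop("stage pool_core_genes produced an empty core set; ",
         "check the GSEA inputs and pooling thresholds")

  say("stage 3/8: glycolysis index + median split")
  combined <- combine_datasets(datasets)
  index <- glycolysis_index(combined, core, alpha = cfg$ssgsea$alpha,
                            normalize = cfg$ssgsea$normalize)
  split <- median_split_by_region(index, combined$metadata)
  write_index_table(index, combined$metadata, split,
                    file.path(cfg$out_dir, "glycolysis_index.tsv"))
  emit("glycolysis_index.tsv")

  say("stage 4/8: differential expression (two contrasts)")
  de_case <- diff_expression(combined, contrast = "case_vs_control",
                             age_df = cfg$de$age_df)
  de_index <- diff_expression(combined, contrast = "high_vs_low_index",
                              split_labels = split, age_df = cfg$de$age_df)
  for (nm in c("de_case_vs_control", "de_high_vs_low_index")) {
    tab <- if (nm == "de_case_vs_control") de_case else de_index
    utils::write.table(as.data.frame(tab)[, c("gene", "log2fc", "t_mod",
                                              "p_value", "fdr")],
                       file.path(cfg$out_dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(paste0(nm, ".tsv"))
  }

  say("stage 5/8: DEG selection and overlap")
  degs_case <- select_degs(de_case, cfg$de$fdr_max, cfg$de$lfc_min)
  degs_index <- select_degs(de_index, cfg$de$fdr_max, cfg$de$lfc_min)
  shared_degs <- overlap_genes(degs_case, degs_index)
  writeLines(degs_case, file.path(cfg$out_dir, "degs_case_vs_control.txt"))
  writeLines(degs_index, file.path(cfg$out_dir, "degs_high_vs_low_index.txt"))
  writeLines(shared_degs, file.path(cfg$out_dir, "degs_overlap.txt"))
  emit("degs_case_vs_control.txt"); emit("degs_high_vs_low_index.txt")
  emit("degs_overlap.txt")

  say("stage 6/8: over-representation analysis")
  background <- Reduce(intersect, lapply(datasets, `[[`, "genes"))
  ora_query <- if (length(shared_degs)) shared_degs else degs_case
  ora <- ora_enrich(ora_query, coll, background)
  utils::write.table(ora, file.path(cfg$out_dir, "ora.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  emit("ora.tsv")

  say("stage 7/8: microenvironment scoring and association")
  marker_scores <- score_markers(combined, markers, alpha = cfg$ssgsea$alpha)
  score_mat <- do.call(cbind, lapply(marker_scores, `[[`, "scores"))
  rownames(score_mat) <- combined$samples
  abund <- nnls_deconvolve(combined, sig, mode = "relative")
  assoc_scores <- microenv_association(score_mat, combined$metadata, index)
  assoc_abund <- microenv_association(unclass(abund), combined$metadata, index)
  utils::write.table(data.frame(sample_id = rownames(score_mat), score_mat),
                     file.path(cfg$out_dir, "marker_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = rownames(abund), unclass(abund)),
                     file.path(cfg$out_dir, "abundance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rbind(cbind(source = "marker_es", assoc_scores),
                           cbind(source = "deconvolution", assoc_abund)),
                     file.path(cfg$out_dir, "microenv_association.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  emit("marker_scores.tsv"); emit("abundance.tsv"); emit("microenv_association.tsv")

  say("stage 8/8: consensus network")
  gly_genes <- unique(unlist(coll$sets))
  marker_genes <- unique(unlist(markers$sets))
  coexpr <- lapply(datasets, coexpr_per_dataset, genes_a = gly_genes,
                   genes_b = marker_genes)
  roles <- c(stats::setNames(rep("glycolysis", length(gly_genes)), gly_genes),
             unlist(lapply(names(markers$sets), function(ct)
               stats::setNames(rep(paste0("marker:", ct),
                                   length(markers$sets[[ct]])),
                               markers$sets[[ct]]))))
  net <- consensus_network(coexpr, ppi, min_support = cfg$network$min_support,
                           require_sign_consistency = cfg$network$sign_consistency,
                           roles = roles)
  write_network(net, file.path(cfg$out_dir, "network.tsv"), "tsv")
  write_network(net, file.path(cfg$out_dir, "network.sif"), "sif")
  emit("network.tsv"); emit("network.sif")

  manifest <- list(
    parameters = cfg[c("gsea", "pooling", "ssgsea", "de", "network")],
    inputs = c(unlist(lapply(cfg$datasets, unlist)), gene_sets = cfg$gene_sets,
               markers = cfg$markers, ppi = cfg$ppi, signature = cfg$signature),
    outputs = stats::setNames(as.character(tools::md5sum(unlist(outputs))),
                              basename(unlist(outputs))),
    n_core_genes = length(core$genes),
    n_degs = c(case_vs_control = length(degs_case),
               high_vs_low_index = length(degs_index),
               overlap = length(shared_degs)),
    n_network_edges = nrow(net$edges))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: ", length(outputs), " stage outputs + manifest.json")
  invisible(list(datasets = datasets, gsea = gsea_res, core = core,
                 index = index, split = split, de_case = de_case,
                 de_index = de_index, degs_case = degs_case,
                 degs_index = degs_index, degs_overlap = shared_degs,
                 ora = ora, marker_scores = marker_scores, abundance = abund,
                 assoc_markers = assoc_scores, assoc_abundance = assoc_abund,
                 network = net, manifest = manifest))
}

#' Build a fixture bundle and a matching pipeline config
#'
#' Convenience wrapper used by the examples and tests: writes the synthetic
#' bundle with [make_fixture_bundle()] and a `config.yaml` pointing at it.
#'
#' @param config a [simulation_config()].
#' @param out_dir directory for the bundle.
#' @param n_perm GSEA permutations recorded in the config.
#' @return the `PipelineConfig`, invisibly.
#' @export
simulate_fixture_bundle <- function(config, out_dir, n_perm = 1000) {
  paths <- make_fixture_bundle(config, out_dir)
  datasets <- stats::setNames(lapply(config$regions, function(r)
    list(expr = paste0("expr_", r, ".tsv"), meta = paste0("meta_", r, ".tsv"))),
    config$regions)
  cfg_list <- list(datasets = datasets,
                   gene_sets = "glycolysis_sets.gmt",
                   markers = "cell_markers.gmt",
                   ppi = "ppi.tsv", signature = "signature.tsv",
                   out_dir = file.path(out_dir, "results"),
                   gsea = list(n_perm = n_perm, seed = config$seed))
  yaml::write_yaml(cfg_list, file.path(out_dir, "config.yaml"))
  cfg_list$base_dir <- normalizePath(out_dir)
  invisible(do.call(pipeline_config, cfg_list))
}
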