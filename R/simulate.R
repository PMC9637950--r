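#' Simulation configuration for multi-region case/control datasets
#'
#' Defines the planted structure of a synthetic study: a shared gene
#' universe across brain regions, a planted case-shifted gene set
#' (negative `effect_size` = downregulated in cases), age and sex covariate
#' effects on random gene subsets, i.i.d. Gaussian log2 noise, optional
#' planted cross-gene correlations, and a seed making everything a pure
#' function of the configuration.
#'
#' Defaults mirror a four-region postmortem case/control design: regions
#' FC/TC/HP/EC, 30 samples per group per region, 30 planted genes
#' downregulated by 0.8 log2 units, residual noise sd 1.0 (typical for log2
#' microarray intensities), ages Uniform(60, 95), balanced sexes.
#'
#' @param n_genes size of the gene universe.
#' @param regions character vector of region names.
#' @param n_per_group samples per group per region.
#' @param planted_set gene symbols receiving the case effect (default
#'   `GLY001..GLY030`).
#' @param effect_size log2-unit shift added to planted genes in cases.
#' @param age_effect per-year slope applied to a random 10% of genes.
#' @param sex_effect shift applied to males for a random 5% of genes.
#' @param noise_sd residual sd in log2 units (> 0).
#' @param coexpr_pairs data.frame `gene_a`, `gene_b`, `rho` of planted
#'   correlations (or NULL).
#' @param mixture_mode whether fixture bundles should include mixture samples.
#' @param seed integer master seed.
#' @return list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_genes = 2000,
                              regions = c("FC", "TC", "HP", "EC"),
                              n_per_group = 30,
                              planted_set = sprintf("GLY%03d", 1:30),
                              effect_size = -0.8,
                              age_effect = 0.01,
                              sex_effect = 0.3,
                              noise_sd = 1.0,
                              coexpr_pairs = NULL,
                              mixture_mode = FALSE,
                              seed = 1) {
  stopifnot(n_genes >= length(planted_set), noise_sd > 0, n_per_group >= 2)
  if (!is.null(coexpr_pairs)) {
    coexpr_pairs <- as.data.frame(coexpr_pairs, stringsAsFactors = FALSE)
    stopifnot(all(c("gene_a", "gene_b", "rho") %in% names(coexpr_pairs)),
              all(abs(coexpr_pairs$rho) < 1))
  }
  structure(list(n_genes = n_genes, regions = regions,
                 n_per_group = n_per_group, planted_set = planted_set,
                 effect_size = effect_size, age_effect = age_effect,
                 sex_effect = sex_effect, noise_sd = noise_sd,
                 coexpr_pairs = coexpr_pairs, mixture_mode = mixture_mode,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

# shared gene universe: a fixed 50-gene glycolysis-like block plus fillers;
# planted genes must be drawn from this universe (checked at generation)
sim_gene_universe <- function(config) {
  n_gly <- min(50, config$n_genes)
  c(sprintf("GLY%03d", seq_len(n_gly)),
    sprintf("G%04d", seq_len(max(config$n_genes - n_gly, 0))))
}

#' Generate one region's case/control expression dataset
#'
#' Log2-scale model: per-gene baseline means drawn `Normal(7, 1.5)`, i.i.d.
#' `Normal(0, noise_sd)` residuals, `effect_size` added to every planted
#' gene in case samples, a linear age effect on a random 10% of genes and a
#' sex shift on a random 5%. Ages are Uniform(60, 95); sexes alternate so
#' groups stay balanced. Fully reproducible given `(config$seed, region)`.
#'
#' @param config a [simulation_config()].
#' @param region one of `config$regions`.
#' @return An [expression_dataset()] with `dataset_id = region`.
#' @export
generate_expression_dataset <- function(config, region) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (!region %in% config$regions) stop("unknown region: ", region)
  genes <- sim_gene_universe(config)
  missing_planted <- setdiff(config$planted_set, genes)
  if (length(missing_planted))
    stop("planted gene(s) not in the gene universe: ",
         paste(missing_planted, collapse = ", "))
  n <- 2 * config$n_per_group
  region_seed <- (as.numeric(config$seed) + 7919 * match(region, config$regions)) %%
    .Machine$integer.max
  with_seed(region_seed, {
    base_mean <- stats::rnorm(length(genes), mean = 7, sd = 1.5)
    age <- stats::runif(n, 60, 95)
    sex <- rep(c("F", "M"), length.out = n)
    group <- rep(c("control", "case"), each = config$n_per_group)
    age_genes <- sample(genes, round(0.10 * length(genes)))
    sex_genes <- sample(genes, round(0.05 * length(genes)))
    vals <- matrix(stats::rnorm(length(genes) * n, sd = config$noise_sd),
                   nrow = length(genes)) + base_mean
    vals[genes %in% config$planted_set, group == "case"] <-
      vals[genes %in% config$planted_set, group == "case"] + config$effect_size
    vals[genes %in% age_genes, ] <- vals[genes %in% age_genes, ] +
      config$age_effect * matrix(age - mean(c(60, 95)),
                                 nrow = sum(genes %in% age_genes),
                                 ncol = n, byrow = TRUE)
    vals[genes %in% sex_genes, sex == "M"] <-
      vals[genes %in% sex_genes, sex == "M"] + config$sex_effect
    rownames(vals) <- genes
    colnames(vals) <- sprintf("%s_S%03d", region, seq_len(n))
    meta <- data.frame(sample_id = colnames(vals), group = group,
                       region = region, age = age, sex = sex,
                       stringsAsFactors = FALSE)
    ds <- expression_dataset(vals, meta, dataset_id = region)
    if (!is.null(config$coexpr_pairs) && nrow(config$coexpr_pairs))
      ds <- plant_coexpression(ds, config$coexpr_pairs,
                               seed = region_seed + 1L)
    ds
  })
}

#' Plant pairwise correlations between existing genes
#'
#' For each pair, the second gene's residuals (deviations from its row mean)
#' are rebuilt as a `rho`-weighted mixture of the first gene's standardized
#' residuals and fresh noise, scaled back to the original residual sd, so
#' the population Pearson/Spearman correlation is approximately `rho`. Other
#' genes are untouched. Pairs sharing a `gene_b` are rejected (the second
#' planting would overwrite the first).
#'
#' @param ds an [expression_dataset()].
#' @param pairs data.frame with `gene_a`, `gene_b`, `rho` (`|rho| < 1`).
#' @param seed integer seed for the fresh-noise component.
#' @return the modified [expression_dataset()].
#' @export
plant_coexpression <- function(ds, pairs, seed = 1) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (any(abs(pairs$rho) >= 1)) stop("|rho| must be < 1")
  unknown <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), ds$genes)
  if (length(unknown)) stop("unknown gene(s) in pairs: ",
                            paste(unknown, collapse = ", "))
  if (anyDuplicated(pairs$gene_b))
    stop("pairs share a gene_b; plantings would overwrite each other")
  with_seed(seed, {
    for (i in seq_len(nrow(pairs))) {
      a <- ds$values[pairs$gene_a[i], ]
      b <- ds$values[pairs$gene_b[i], ]
      rho <- pairs$rho[i]
      za <- as.numeric(scale(a))
      sd_b <- stats::sd(b)
      noise <- stats::rnorm(length(b))
      new_resid <- (rho * za + sqrt(1 - rho^2) * noise) * sd_b
      ds$values[pairs$gene_b[i], ] <- mean(b) + new_resid
    }
  })
  ds
}

#' Generate bulk samples as mixtures of signature profiles
#'
#' Linear-scale expression is `signature %*% t(proportions)`, perturbed by
#' multiplicative log-normal noise (`sdlog = noise_sd`), then loaded as
#' `log2(x + 1)`. The ground-truth proportions are attached as the
#' `proportions` attribute.
#'
#' @param sig a [signature_matrix()].
#' @param proportions samples x cell types matrix; rows sum to 1 (tolerance
#'   1e-8), entries >= 0.
#' @param noise_sd sdlog of the multiplicative noise (0 = noiseless).
#' @param seed integer seed.
#' @return An [expression_dataset()] (`region = "MIX"`, all controls) with
#'   attribute `proportions`.
#' @export
generate_mixture_samples <- function(sig, proportions, noise_sd = 0.1, seed = 1) {
  stopifnot(inherits(sig, "SignatureMatrix"), is.matrix(proportions))
  if (ncol(proportions) != length(sig$cell_types))
    stop("proportions columns must match signature cell types")
  if (any(proportions < 0)) stop("proportions must be >= 0")
  bad <- abs(rowSums(proportions) - 1) > 1e-8
  if (any(bad)) stop("proportion row(s) do not sum to 1: ",
                     paste(which(bad), collapse = ", "))
  n <- nrow(proportions)
  lin <- sig$values %*% t(proportions)          # genes x samples
  vals <- with_seed(seed, {
    if (noise_sd > 0)
      lin <- lin * matrix(stats::rlnorm(length(lin), 0, noise_sd), nrow = nrow(lin))
    log2(lin + 1)
  })
  colnames(vals) <- sprintf("MIX_S%03d", seq_len(n))
  rownames(vals) <- sig$genes
  meta <- data.frame(sample_id = colnames(vals), group = "control",
                     region = "MIX", age = 70,
                     sex = rep(c("F", "M"), length.out = n),
                     stringsAsFactors = FALSE)
  ds <- expression_dataset(vals, meta, dataset_id = "mixture")
  rownames(proportions) <- colnames(vals)
  colnames(proportions) <- sig$cell_types
  attr(ds, "proportions") <- proportions
  ds
}

# seven overlapping glycolysis-like sets (sizes 10-40) over the 50-gene
# glycolysis universe; every universe gene lands in >= 2 sets, mimicking the
# heavy redundancy of the curated glycolysis collections
sim_gene_sets <- function(config) {
  genes <- sim_gene_universe(config)
  gly <- genes[startsWith(genes, "GLY")]
  sizes <- c(40, 35, 30, 25, 20, 15, 10)
  with_seed(config$seed + 101L, {
    sets <- lapply(sizes, function(s) sort(sample(gly, s)))
    names(sets) <- sprintf("GLYCOLYSIS_SET_%d", seq_along(sets))
    counts <- table(factor(unlist(sets), levels = gly))
    under <- names(counts)[counts < 2]
    # patch coverage: add under-covered genes to the two largest sets
    for (g in under) {
      hosts <- which(!vapply(sets, function(s) g %in% s, TRUE))[1:2]
      hosts <- hosts[!is.na(hosts)]
      for (h in hosts) sets[[h]] <- sort(union(sets[[h]], g))
    }
    gene_set_collection(sets, source = "simulated")
  })
}

# marker sets for six brain cell types drawn from the filler genes
sim_marker_sets <- function(config, n_markers = 8) {
  genes <- sim_gene_universe(config)
  filler <- genes[!startsWith(genes, "GLY")]
  types <- c("astrocyte", "endothelial", "microglia", "neuron",
             "oligodendrocyte", "OPC")
  if (length(filler) < n_markers * length(types))
    stop("gene universe too small for marker sets")
  sets <- lapply(seq_along(types), function(i)
    filler[((i - 1) * n_markers + 1):(i * n_markers)])
  names(sets) <- types
  gene_set_collection(sets, source = "simulated")
}

# signature matrix over the marker genes: own markers high, background low
sim_signature <- function(config, high = 400, low = 8) {
  markers <- sim_marker_sets(config)
  genes <- unlist(markers$sets, use.names = FALSE)
  types <- names(markers$sets)
  vals <- matrix(low, nrow = length(genes), ncol = length(types),
                 dimnames = list(genes, types))
  with_seed(config$seed + 202L, {
    for (ct in types)
      vals[markers$sets[[ct]], ct] <- high * stats::runif(length(markers$sets[[ct]]),
                                                          0.6, 1.4)
  })
  signature_matrix(vals)
}

# default planted cross-gene correlations: 10 glycolysis-marker pairs at
# rho 0.7, matching the consensus-network fixture
sim_default_pairs <- function(config) {
  markers <- sim_marker_sets(config)
  marker_genes <- unlist(lapply(markers$sets, `[`, 1:2), use.names = FALSE)
  data.frame(gene_a = config$planted_set[1:10],
             gene_b = marker_genes[1:10],
             rho = 0.7, stringsAsFactors = FALSE)
}

#' Write a complete synthetic fixture bundle
#'
#' Generates and writes everything the pipeline consumes: per-region
#' expression and metadata TSVs (with planted correlations), the
#' seven-set glycolysis-like GMT, the six-cell-type marker GMT, a PPI TSV
#' containing 6 of the 10 planted pairs (plus decoy edges and sub-threshold
#' edges), the cell signature TSV, mixture samples when `mixture_mode`, and
#' a `ground_truth.json` recording the planted genes, pairs and (if any)
#' mixture proportions. Two calls with the same config produce
#' byte-identical files.
#'
#' @param config a [simulation_config()]; if its `coexpr_pairs` is NULL the
#'   default 10-pair planting is used.
#' @param out_dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
make_fixture_bundle <- function(config, out_dir) {
  stopifnot(inherits(config, "SimulationConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(config$coexpr_pairs)) config$coexpr_pairs <- sim_default_pairs(config)
  paths <- list()
  for (r in config$regions) {
    ds <- generate_expression_dataset(config, r)
    ep <- file.path(out_dir, paste0("expr_", r, ".tsv"))
    mp <- file.path(out_dir, paste0("meta_", r, ".tsv"))
    write_expression_dataset(ds, ep, mp)
    paths[[paste0("expr_", r)]] <- ep
    paths[[paste0("meta_", r)]] <- mp
  }
  gmt <- file.path(out_dir, "glycolysis_sets.gmt")
  write_gmt(sim_gene_sets(config), gmt)
  paths$gene_sets <- gmt
  mgmt <- file.path(out_dir, "cell_markers.gmt")
  markers <- sim_marker_sets(config)
  write_gmt(markers, mgmt)
  paths$markers <- mgmt
  # PPI: 6 of the 10 planted pairs at high confidence, plus decoys and
  # below-threshold edges that read_ppi_table() must drop
  pr <- config$coexpr_pairs
  genes <- sim_gene_universe(config)
  ppi_edges <- with_seed(config$seed + 303L, {
    decoy_a <- sample(genes, 20)
    decoy_b <- sample(setdiff(genes, decoy_a), 20)
    rbind(data.frame(gene_a = pr$gene_a[1:6], gene_b = pr$gene_b[1:6],
                     score = 0.9, stringsAsFactors = FALSE),
          data.frame(gene_a = decoy_a[1:10], gene_b = decoy_b[1:10],
                     score = 0.85, stringsAsFactors = FALSE),
          data.frame(gene_a = decoy_a[11:20], gene_b = decoy_b[11:20],
                     score = 0.4, stringsAsFactors = FALSE))
  })
  ppi_path <- file.path(out_dir, "ppi.tsv")
  utils::write.table(ppi_edges, ppi_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$ppi <- ppi_path
  sig <- sim_signature(config)
  sig_path <- file.path(out_dir, "signature.tsv")
  write_signature_matrix(sig, sig_path)
  paths$signature <- sig_path
  truth <- list(planted_set = config$planted_set,
                effect_size = config$effect_size,
                coexpr_pairs = pr,
                ppi_planted = pr[1:6, c("gene_a", "gene_b")],
                regions = config$regions,
                seed = config$seed)
  if (isTRUE(config$mixture_mode)) {
    props <- with_seed(config$seed + 404L, {
      p <- matrix(stats::rgamma(20 * length(sig$cell_types), 1), nrow = 20)
      p / rowSums(p)
    })
    mix <- generate_mixture_samples(sig, props, noise_sd = 0.1,
                                    seed = config$seed + 405L)
    write_expression_dataset(mix, file.path(out_dir, "expr_MIX.tsv"),
                             file.path(out_dir, "meta_MIX.tsv"))
    paths$mixture <- file.path(out_dir, "expr_MIX.tsv")
    truth$mixture_proportions <- as.data.frame(attr(mix, "proportions"))
  }
  gt_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(truth, gt_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths$ground_truth <- gt_path
  invisible(paths)
}
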