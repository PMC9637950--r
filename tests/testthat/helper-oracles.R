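# Independent oracles: deliberately naive per-position / combinatorial
# implementations used only to check the package's optimized code paths.

# naive weighted Kolmogorov-Smirnov running sum, one position at a time
oracle_running_es <- function(metric, in_set, weight) {
  n <- length(metric)
  denom <- sum(abs(metric[in_set])^weight)
  n_miss <- n - sum(in_set)
  ph <- 0; pm <- 0
  curve <- numeric(n)
  for (i in seq_len(n)) {
    if (in_set[i]) ph <- ph + abs(metric[i])^weight / denom
    else pm <- pm + 1 / n_miss
    curve[i] <- ph - pm
  }
  i <- which.max(abs(curve))
  list(es = curve[i], curve = curve, extremum_index = i)
}

# naive single-sample enrichment score: explicit sort + per-position loop
oracle_ssgsea <- function(values, genes, gene_set, alpha) {
  ord <- order(-values, genes, method = "radix")
  in_set <- genes[ord] %in% gene_set
  n <- length(values)
  v <- (n:1)^alpha
  denom <- sum(v[in_set])
  n_out <- n - sum(in_set)
  pin <- 0; pout <- 0; total <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) pin <- pin + v[i] / denom else pout <- pout + 1 / n_out
    total <- total + (pin - pout)
  }
  total
}

# step-up Benjamini-Hochberg evaluated directly from the formula
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj_sorted <- p[ord] * n / seq_len(n)
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  pmin(adj_sorted, 1)[order(ord)]
}

# hypergeometric upper-tail probability by direct combinatorial summation
oracle_hyper_tail <- function(N, K, n, k) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# brute-force evaluator of the consensus retention rule for one pair:
# sig_flags = logical per dataset, signs = rho sign per dataset (only
# meaningful where sig), in_ppi = logical, min_support, consistency flag.
oracle_consensus_keep <- function(sig_flags, signs, in_ppi, min_support,
                                  require_sign_consistency) {
  support <- sum(sig_flags) + in_ppi
  if (support < min_support) return(FALSE)
  if (!any(sig_flags)) return(FALSE)               # sign undefined
  sg <- unique(signs[sig_flags])
  if (require_sign_consistency && length(sg) > 1) return(FALSE)
  TRUE
}

# small deterministic expression dataset built in code
make_tiny_ds <- function(n_genes = 60, n_per_group = 10, seed = 42,
                         effect = 0, planted = character()) {
  cfg <- simulation_config(n_genes = n_genes,
                           regions = "FC",
                           n_per_group = n_per_group,
                           planted_set = if (length(planted)) planted else "GLY001",
                           effect_size = effect,
                           age_effect = 0, sex_effect = 0,
                           noise_sd = 1, seed = seed)
  generate_expression_dataset(cfg, "FC")
}

expect_association <- function(obj) {
  expect_s3_class(obj, "AssociationResult")
  expect_true(is.finite(obj$p_value) || is.na(obj$p_value))
}
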