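test_that("natural spline basis has the requested dimension and spans affine changes", {
  x <- runif(100, 60, 95)
  b1 <- natural_spline_basis(x, df = 1)
  expect_equal(ncol(b1), 1L)
  b3 <- natural_spline_basis(x, df = 3)
  expect_equal(ncol(b3), 3L)
  expect_equal(qr(cbind(1, b3))$rank, 4L)
  expect_error(natural_spline_basis(rep(5, 10)), "constant")
  # span property: rescaling the input leaves fitted values unchanged
  y <- sin(x / 10) + rnorm(100, 0, 0.01)
  f1 <- fitted(lm(y ~ natural_spline_basis(x, 2)))
  f2 <- fitted(lm(y ~ natural_spline_basis((x - 60) / 35, 2)))
  expect_equal(f1, f2, tolerance = 1e-8)
})

test_that("design matrix has the documented columns and detects collinearity", {
  meta <- data.frame(sample_id = sprintf("s%02d", 1:16),
                     group = rep(c("control", "case"), 8),
                     region = rep(c("EC", "FC", "HP", "TC"), each = 4),
                     age = c(61, 72, 65, 80, 70, 62, 85, 90,
                             66, 77, 68, 83, 64, 79, 73, 88),
                     sex = rep(c("F", "F", "M", "M"), 4))
  d <- build_design(meta, "case_vs_control")
  # intercept + case + 3 region dummies + sexM + age spline = 7
  expect_equal(ncol(d$values), 7L)
  expect_equal(d$contrast_column, "case")
  expect_true(all(c("regionFC", "regionHP", "regionTC", "sexM") %in%
                    colnames(d$values)))
  expect_false("regionEC" %in% colnames(d$values))  # first alphabetical = reference

  single <- meta[meta$region == "FC", ]
  d1 <- build_design(single, "case_vs_control")
  expect_equal(ncol(d1$values), 4L)                  # no region dummies

  conf <- meta
  conf$group <- ifelse(conf$region == "EC", "case", "control")
  conf$region <- ifelse(conf$region == "EC", "EC", "FC")
  expect_error(build_design(conf, "case_vs_control"), "rank-deficient")

  labels <- setNames(rep(c("low", "high"), 8), meta$sample_id)
  dh <- build_design(meta, "high_vs_low_index", split_labels = labels)
  expect_equal(dh$contrast_column, "high")
  expect_error(build_design(meta, "high_vs_low_index"), "split_labels")
})

test_that("per-gene OLS equals the normal-equation solution on a hand toy", {
  # 4 samples, intercept + contrast design; solvable by hand
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     group = c("control", "control", "case", "case"),
                     region = "FC", age = c(60, 70, 80, 90), sex = "F")
  vals <- rbind(g1 = c(1, 3, 6, 8), g2 = c(2, 2, 2, 2),
                g3 = c(0, 1, 10, 11), g4 = c(5, 4, 3, 2),
                g5 = c(1, 1, 2, 2), g6 = c(0, 0, 1, 1),
                g7 = c(3, 1, 4, 2), g8 = c(1, 2, 3, 4),
                g9 = c(2, 4, 6, 8), g10 = c(9, 7, 5, 3))
  colnames(vals) <- meta$sample_id
  ds <- expression_dataset(vals, meta, "toy")
  x <- cbind(1, c(0, 0, 1, 1))
  design <- structure(list(values = `colnames<-`(x, c("intercept", "case")),
                           contrast_column = "case"), class = "DesignMatrix")
  fits <- fit_linear_models(ds, design)
  beta_hat <- solve(t(x) %*% x, t(x) %*% t(vals))
  expect_equal(fits$log2fc, unname(beta_hat[2, ]), tolerance = 1e-12)
  expect_equal(fits$df_resid, 2)
  # g1: residuals (-1,1,-1,1) -> sigma2 = 4/2 = 2
  expect_equal(fits$sigma2[1], 2, tolerance = 1e-12)
  expect_equal(fits$sigma2[2], 0)                   # exact fit
  expect_equal(fits$v_contrast, 1, tolerance = 1e-12)  # 1/2 + 1/2
})

test_that("planted log2 fold changes are estimated without bias", {
  cfg <- simulation_config(n_genes = 1000, n_per_group = 40, effect_size = 1,
                           planted_set = sprintf("GLY%03d", 1:30),
                           noise_sd = 0.3, seed = 55)
  ds <- generate_expression_dataset(cfg, "FC")
  tab <- diff_expression(ds)
  planted <- tab$log2fc[tab$gene %in% cfg$planted_set]
  expect_lt(abs(mean(planted) - 1), 0.1)
})

test_that("eBayes moderation reproduces the documented limiting cases", {
  ds <- make_tiny_ds(n_genes = 200, n_per_group = 10, seed = 61)
  design <- build_design(ds$metadata, "case_vs_control")
  fits <- fit_linear_models(ds, design)
  # equal observed variances -> d0 at cap, all posterior variances = s0^2
  fits_eq <- fits
  fits_eq$sigma2 <- rep(0.5, length(fits$sigma2))
  tab_eq <- moderate_ebayes(fits_eq)
  expect_equal(attr(tab_eq, "d0"), 1e6)
  expect_equal(unique(round(tab_eq$s2_post, 10)),
               round(attr(tab_eq, "s0_2"), 10))
  # finite d0: moderated t follows the posterior-variance formula and
  # correlates with (but shrinks relative to) the ordinary t statistic
  ds_het <- ds
  sd_g <- with_seed(62, sqrt(1 / stats::rgamma(nrow(ds$values), 2, rate = 2)))
  ds_het$values <- 7 + (ds_het$values - 7) * sd_g
  fits_h <- fit_linear_models(ds_het, design)
  tab <- moderate_ebayes(fits_h)
  d0 <- attr(tab, "d0")
  expect_lt(d0, 1e6)
  t_ord <- fits_h$log2fc / sqrt(fits_h$sigma2 * fits_h$v_contrast)
  t_limit <- fits_h$log2fc /
    sqrt(((d0 * attr(tab, "s0_2") + fits_h$df_resid * fits_h$sigma2) /
            (d0 + fits_h$df_resid)) * fits_h$v_contrast)
  expect_equal(tab$t_mod, t_limit, tolerance = 1e-12)
  expect_gt(cor(tab$t_mod, t_ord), 0.95)
  expect_error(moderate_ebayes(structure(list(gene = "g", log2fc = 1,
                                              sigma2 = 1, df_resid = 2,
                                              v_contrast = 1),
                                         class = "GeneFits")),
               ">= 10 genes")
})

test_that("moderated statistics agree with limma's empirical Bayes", {
  skip_if_not_installed("limma")
  # heterogeneous true variances so the prior df is finite and the moment
  # estimator actually shrinks
  ds <- make_tiny_ds(n_genes = 500, n_per_group = 15, seed = 99)
  sd_g <- with_seed(100, sqrt(1 / stats::rgamma(nrow(ds$values), 2, rate = 2)))
  ds$values <- 7 + (ds$values - 7) * sd_g
  design <- build_design(ds$metadata, "case_vs_control")
  mine <- moderate_ebayes(fit_linear_models(ds, design))
  lfit <- limma::eBayes(limma::lmFit(ds$values, design$values))
  expect_equal(attr(mine, "d0"), lfit$df.prior, tolerance = 1e-6)
  expect_equal(attr(mine, "s0_2"), lfit$s2.prior, tolerance = 1e-6)
  expect_equal(mine$t_mod, lfit$t[, "case"], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(mine$p_value, lfit$p.value[, "case"], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("null p-values are uniform under no differential expression", {
  cfg <- simulation_config(n_genes = 2000, n_per_group = 20, effect_size = 0,
                           age_effect = 0, sex_effect = 0, seed = 71)
  ds <- generate_expression_dataset(cfg, "FC")
  tab <- diff_expression(ds)
  expect_gt(stats::ks.test(tab$p_value, "punif")$p.value, 0.01)
})

test_that("BH adjustment matches the step-up formula and is order-invariant", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(12)
  for (i in 1:25) {
    p <- runif(sample(1:200, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))          # adjustment never shrinks p
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm]), adj[perm], tolerance = 1e-12)
  }
})

test_that("DEG selection applies strict thresholds and overlap is exact", {
  tab <- data.frame(gene = paste0("g", 1:5),
                    fdr = c(0.04, 0.05, 0.04, 0.04, 0.2),
                    log2fc = c(0.6, 0.6, 0.5, -0.7, 2))
  class(tab) <- c("DiffExprTable", "data.frame")
  expect_equal(select_degs(tab, 0.05, 0.5), c("g1", "g4"))
  tab$fdr <- 1
  expect_length(select_degs(tab, 0.05, 0.5), 0)
  # monotonicity: raising lfc_min never adds genes
  tab2 <- data.frame(gene = paste0("g", 1:50), fdr = runif(50),
                     log2fc = rnorm(50))
  class(tab2) <- c("DiffExprTable", "data.frame")
  expect_true(all(select_degs(tab2, 0.5, 1.0) %in% select_degs(tab2, 0.5, 0.5)))

  expect_equal(overlap_genes(c("b", "a"), c("a", "b")), c("a", "b"))
  expect_length(overlap_genes("a", "z"), 0)
  set.seed(3)
  a <- sample(sprintf("g%03d", 1:300), 100)
  b <- sample(sprintf("g%03d", 1:300), 100)
  expect_equal(length(overlap_genes(a, b)), sum(a %in% b))
})

test_that("region adjustment removes confounded false positives (paired assertion)", {
  # plant a region-level shift uncorrelated with disease: region B is shifted
  # +1 on 10% of genes and has more cases, confounding group with region
  set.seed(202)
  n_genes <- 800
  genes <- sprintf("g%04d", 1:n_genes)
  n_a <- 60; n_b <- 60
  grp <- c(rep("control", 45), rep("case", 15), rep("control", 15), rep("case", 45))
  region <- c(rep("A", n_a), rep("B", n_b))
  vals <- matrix(rnorm(n_genes * (n_a + n_b), 7, 1), nrow = n_genes,
                 dimnames = list(genes, sprintf("s%03d", 1:(n_a + n_b))))
  shifted <- sample(genes, 80)
  vals[shifted, region == "B"] <- vals[shifted, region == "B"] + 1
  meta <- data.frame(sample_id = colnames(vals), group = grp, region = region,
                     age = runif(n_a + n_b, 60, 95),
                     sex = rep(c("F", "M"), 60))
  ds <- expression_dataset(vals, meta, "confounded")
  with_region <- diff_expression(ds)
  n_with <- length(select_degs(with_region, 0.05, 0.5))
  # omit the region covariate: fit on a metadata copy with one region
  meta_no <- meta; meta_no$region <- "A"
  ds_no <- expression_dataset(vals, meta_no, "unadjusted")
  without_region <- diff_expression(ds_no)
  n_without <- length(select_degs(without_region, 0.05, 0.5))
  expect_lte(n_with, 3)           # ~nominal: no true group effect exists
  expect_gt(n_without, 20)        # confounding leaks into the contrast
})
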