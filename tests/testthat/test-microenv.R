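test_that("Wilcoxon comparison matches the exact enumeration on small samples", {
  # all case values strictly above control, n = 4 + 4: the most extreme
  # arrangement has exact two-sided p = 2 / choose(8, 4)
  values <- c(10, 11, 12, 13, 1, 2, 3, 4)
  labels <- rep(c("case", "control"), each = 4)
  res <- compare_groups(values, labels)
  expect_equal(res$p_value, 2 / choose(8, 4), tolerance = 1e-12)
  expect_gt(res$directed_log_p, 0)
  # label swap flips the direction, not the p-value
  swapped <- compare_groups(values, rev(labels))
  expect_equal(swapped$p_value, res$p_value, tolerance = 1e-12)
  expect_equal(swapped$directed_log_p, -res$directed_log_p, tolerance = 1e-12)
  # identical value sets: no signal
  same <- compare_groups(rep(1, 8), labels)
  expect_equal(same$p_value, 1)
  expect_equal(same$directed_log_p, 0)
  expect_error(compare_groups(1:3, c("case", "control", "control")), ">= 2")
})

test_that("large-sample Wilcoxon uses the tie-corrected normal approximation", {
  set.seed(5)
  x <- round(rnorm(30, 1), 1); y <- round(rnorm(30), 1)   # forced ties
  res <- compare_groups(c(x, y), rep(c("case", "control"), each = 30))
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("Spearman association is monotone-invariant with the t approximation", {
  x <- c(0.3, 1.2, 2.4, 3.1, 4.8, 5.5, 7.2, 8.9)
  expect_equal(spearman_assoc(x, x^3)$rho, 1)        # monotone transform
  expect_equal(spearman_assoc(x, -x)$rho, -1)
  expect_error(spearman_assoc(x, rep(2, 8)), "constant")
  expect_error(spearman_assoc(1:3, 3:1), "n >= 4")
  set.seed(6)
  a <- rnorm(25); b <- 0.5 * a + rnorm(25)
  res <- spearman_assoc(a, b)
  rho <- cor(a, b, method = "spearman")
  tstat <- rho * sqrt(23 / (1 - rho^2))
  expect_equal(res$p_value, 2 * pt(-abs(tstat), 23), tolerance = 1e-12)
})

test_that("a planted correlation is detected at the expected strength", {
  ds <- make_tiny_ds(n_genes = 120, n_per_group = 30, seed = 44)
  ds <- plant_coexpression(ds, data.frame(gene_a = "G0001", gene_b = "G0002",
                                          rho = 0.7), seed = 9)
  res <- spearman_assoc(ds$values["G0001", ], ds$values["G0002", ])
  expect_lt(abs(res$rho - 0.7), 0.2)
  expect_lt(res$p_value, 0.05)
})

test_that("NNLS deconvolution recovers pure, noiseless and noisy mixtures", {
  cfg <- simulation_config(n_genes = 200, n_per_group = 4, seed = 12)
  sig <- glycoindex:::sim_signature(cfg)
  k <- length(sig$cell_types)
  # pure samples
  pure <- generate_mixture_samples(sig, diag(k), noise_sd = 0, seed = 1)
  ab <- nnls_deconvolve(pure, sig, mode = "relative")
  expect_equal(unname(unclass(ab)), diag(k), tolerance = 1e-6,
               ignore_attr = TRUE)
  # noiseless two-type mixture: exact recovery
  p <- matrix(0, 2, k); p[1, 1:2] <- c(0.3, 0.7); p[2, 3:4] <- c(0.5, 0.5)
  mix <- generate_mixture_samples(sig, p, noise_sd = 0, seed = 1)
  ab2 <- nnls_deconvolve(mix, sig, mode = "relative")
  expect_lt(max(abs(unclass(ab2) - p)), 1e-6)
  # noisy mixtures: mean absolute error under 0.05
  set.seed(31)
  pn <- matrix(rgamma(20 * k, 1), 20); pn <- pn / rowSums(pn)
  mixn <- generate_mixture_samples(sig, pn, noise_sd = 0.1, seed = 2)
  abn <- nnls_deconvolve(mixn, sig, mode = "relative")
  expect_lt(mean(abs(unclass(abn) - pn)), 0.05)
  # relative rows sum to one
  expect_equal(unname(rowSums(unclass(abn))), rep(1, 20), tolerance = 1e-8)
})

test_that("absolute-mode coefficients are scale-equivariant", {
  cfg <- simulation_config(n_genes = 200, n_per_group = 4, seed = 12)
  sig <- glycoindex:::sim_signature(cfg)
  k <- length(sig$cell_types)
  p <- matrix(1 / k, 3, k)
  mix <- generate_mixture_samples(sig, p, noise_sd = 0, seed = 3)
  ab1 <- nnls_deconvolve(mix, sig, mode = "absolute")
  doubled <- mix
  doubled$values <- log2(2 * (2^mix$values - 1) + 1)   # double linear expression
  ab2 <- nnls_deconvolve(doubled, sig, mode = "absolute")
  expect_equal(unclass(ab2), 2 * unclass(ab1), tolerance = 1e-6)
  # rank-deficient signature is rejected
  dup <- sig$values; dup[, 2] <- dup[, 1]
  expect_error(nnls_deconvolve(mix, signature_matrix(dup)), "rank-deficient")
})

test_that("marker scores rise with the planted cell fraction and agree with NNLS", {
  cfg <- simulation_config(n_genes = 200, n_per_group = 4, seed = 12)
  sig <- glycoindex:::sim_signature(cfg)
  markers <- glycoindex:::sim_marker_sets(cfg)
  k <- length(sig$cell_types)
  # microglia fraction sweeps 0.05..0.75, remainder spread evenly
  fr <- seq(0.05, 0.75, length.out = 15)
  props <- t(vapply(fr, function(f) {
    p <- rep((1 - f) / (k - 1), k); p[3] <- f; p
  }, numeric(k)))
  mix <- generate_mixture_samples(sig, props, noise_sd = 0.1, seed = 21)
  scores <- score_markers(mix, markers)
  expect_named(scores, markers_names <- names(markers$sets))
  mg <- scores[["microglia"]]$scores
  expect_gte(cor(mg, fr, method = "spearman"), 0.8)
  # deconvolution ranks samples concordantly for the swept cell type
  ab <- nnls_deconvolve(mix, sig, mode = "relative")
  expect_gte(cor(mg, unclass(ab)[, "microglia"], method = "spearman"), 0.7)
  # identical marker sets give identical scores
  twin <- gene_set_collection(list(a = markers$sets[[1]], b = markers$sets[[1]]))
  tw <- score_markers(mix, twin)
  expect_equal(tw$a$scores, tw$b$scores)
})

test_that("adjusted association nests the simple regression and flags separation", {
  set.seed(61)
  x <- rnorm(40); y <- 0.8 * x + rnorm(40)
  plain <- adjusted_assoc(y, x, covariates = NULL, family = "linear")
  ref <- summary(lm(y ~ x))$coefficients
  expect_equal(plain$statistic, ref["x", "t value"], tolerance = 1e-10)
  expect_equal(plain$p_value, ref["x", "Pr(>|t|)"], tolerance = 1e-10)
  # adjusting for the true confounder kills a spurious association
  z <- rnorm(40); x2 <- z + rnorm(40, 0, 0.3); y2 <- z + rnorm(40, 0, 0.3)
  unadj <- adjusted_assoc(y2, x2, NULL, "linear")
  adj <- adjusted_assoc(y2, x2, data.frame(z = z), "linear")
  expect_lt(unadj$p_value, 0.01)
  expect_gt(adj$p_value, unadj$p_value)
  # perfect separation in the logistic family is flagged, not mis-reported
  sep <- adjusted_assoc(c(rep(0, 10), rep(1, 10)), c(rnorm(10), rnorm(10) + 50),
                        NULL, "logistic")
  expect_true(is.na(sep$p_value))
  expect_true(sep$separation)
})

test_that("logistic association detects a planted index effect in most replicates", {
  hits <- 0
  for (rep_i in 1:10) {
    sim <- with_seed(1000 + rep_i, {
      x <- rnorm(200)
      pr <- plogis(log(2) * x)        # odds ratio 2 per SD
      y <- rbinom(200, 1, pr)
      age <- runif(200, 60, 95)
      list(x = x, y = y, age = age)
    })
    res <- adjusted_assoc(sim$y, sim$x, data.frame(age = sim$age), "logistic")
    if (!is.na(res$p_value) && res$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("abundance-group association reproduces the planted direction", {
  cfg <- simulation_config(n_genes = 200, n_per_group = 4, seed = 12)
  sig <- glycoindex:::sim_signature(cfg)
  k <- length(sig$cell_types)
  # cases get systematically more microglia
  n <- 40
  grp <- rep(c("control", "case"), each = n / 2)
  props <- t(vapply(seq_len(n), function(i) {
    f <- if (grp[i] == "case") 0.5 else 0.2
    p <- rep((1 - f) / (k - 1), k); p[3] <- f; p
  }, numeric(k)))
  mix <- generate_mixture_samples(sig, props, noise_sd = 0.1, seed = 77)
  mix$metadata$group <- grp
  ab <- nnls_deconvolve(mix, sig, mode = "relative")
  assoc <- microenv_association(unclass(ab), mix$metadata)
  mg_row <- assoc[assoc$cell_type == "microglia", ]
  expect_gt(mg_row$directed_log_p, 0)
  expect_lt(mg_row$p_value, 0.01)
})
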