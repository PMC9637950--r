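#' Natural cubic spline basis for a covariate
#'
#' Wraps [splines::ns()]: boundary knots at the data range, interior knots
#' at quantiles when `df > 1`. With `df = 1` (the default used for donor
#' age) this yields a single smooth basis column.
#'
#' @param values numeric vector with >= 2 distinct values.
#' @param df degrees of freedom (>= 1); number of basis columns.
#' @return numeric matrix with `df` columns.
#' @export
natural_spline_basis <- function(values, df = 1) {
  stopifnot(df >= 1)
  if (length(unique(values)) < 2)
    stop("spline covariate is constant; cannot build a basis")
  basis <- splines::ns(values, df = df)
  mat <- unclass(basis)[, , drop = FALSE]
  colnames(mat) <- paste0("spline", seq_len(ncol(mat)))
  attributes(mat)[setdiff(names(attributes(mat)), c("dim", "dimnames"))] <- NULL
  mat
}

#' Build a covariate-adjusted design matrix
#'
#' Intercept + contrast indicator + region dummies + sex dummy + natural
#' cubic spline of age. Reference levels are fixed for sign-stable
#' coefficients: first region alphabetically, sex F, group control (or split
#' label `low`). The contrast column is 1 for case (or `high` index).
#'
#' @param meta sample metadata (`sample_id`, `group`, `region`, `age`, `sex`).
#' @param contrast `"case_vs_control"` or `"high_vs_low_index"`.
#' @param split_labels named `"low"`/`"high"` vector (from
#'   [median_split_by_region()]); required for `high_vs_low_index`.
#' @param age_df spline degrees of freedom for age (default 1).
#' @return A `DesignMatrix`: list with `values` (samples x columns matrix)
#'   and `contrast_column` (name of the tested coefficient).
#' @export
build_design <- function(meta, contrast = c("case_vs_control", "high_vs_low_index"),
                         split_labels = NULL, age_df = 1) {
  contrast <- match.arg(contrast)
  n <- nrow(meta)
  if (contrast == "case_vs_control") {
    cvec <- as.numeric(meta$group == "case")
    cname <- "case"
  } else {
    if (is.null(split_labels)) stop("high_vs_low_index contrast needs split_labels")
    lab <- split_labels[meta$sample_id]
    if (anyNA(lab)) stop("split_labels missing for sample(s): ",
                         paste(meta$sample_id[is.na(lab)], collapse = ", "))
    cvec <- as.numeric(lab == "high")
    cname <- "high"
  }
  cols <- list(intercept = rep(1, n))
  cols[[cname]] <- cvec
  regions <- sort(unique(meta$region))
  for (r in regions[-1]) cols[[paste0("region", r)]] <- as.numeric(meta$region == r)
  if (length(unique(meta$sex)) > 1) cols[["sexM"]] <- as.numeric(meta$sex == "M")
  sp <- natural_spline_basis(meta$age, df = age_df)
  colnames(sp) <- paste0("age_", colnames(sp))
  x <- cbind(do.call(cbind, cols), sp)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    bad <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    stop("design matrix is rank-deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(values = x, contrast_column = cname), class = "DesignMatrix")
}

#' Per-gene ordinary least squares fits
#'
#' Fits every gene's log2 expression on the design with one QR
#' decomposition shared across genes. The contrast coefficient is the log2
#' fold change; residual variance and degrees of freedom feed the
#' empirical-Bayes moderation step.
#'
#' @param ds an [expression_dataset()] whose samples match the design rows.
#' @param design a `DesignMatrix` from [build_design()].
#' @return list of class `GeneFits`: `gene`, `log2fc`, `sigma2`, `df_resid`,
#'   `v_contrast` (unscaled variance of the contrast coefficient).
#' @export
fit_linear_models <- function(ds, design) {
  stopifnot(inherits(ds, "ExpressionDataset"), inherits(design, "DesignMatrix"))
  x <- design$values
  if (nrow(x) != length(ds$samples))
    stop("design rows (", nrow(x), ") do not match samples (", length(ds$samples), ")")
  if (nrow(x) <= ncol(x)) stop("need more samples than design columns")
  y <- t(ds$values)                      # samples x genes
  qrx <- qr(x)
  coefs <- qr.coef(qrx, y)               # columns x genes
  resid <- qr.resid(qrx, y)
  df <- nrow(x) - qrx$rank
  if (df < 1) stop("zero residual degrees of freedom")
  sigma2 <- colSums(resid^2) / df
  xtx_inv <- chol2inv(qr.R(qrx)[, order(qrx$pivot), drop = FALSE])
  ci <- match(design$contrast_column, colnames(x))
  structure(list(gene = ds$genes,
                 log2fc = unname(coefs[design$contrast_column, ]),
                 sigma2 = unname(sigma2),
                 df_resid = df,
                 v_contrast = xtx_inv[ci, ci]),
            class = "GeneFits")
}

# invert trigamma by Newton iteration (monotone decreasing on (0, Inf))
trigamma_inverse <- function(y, tol = 1e-8, max_iter = 100) {
  if (y <= 0) return(Inf)
  x <- 0.5 + 1 / y                      # starting value, good for all y > 0
  for (i in seq_len(max_iter)) {
    f <- trigamma(x) - y
    step <- f / psigamma(x, 2)          # Newton on trigamma
    x_new <- x - step
    if (x_new <= 0) x_new <- x / 2
    if (abs(x_new - x) < tol * x) return(x_new)
    x <- x_new
  }
  x
}

#' Empirical-Bayes variance moderation and moderated t-statistics
#'
#' Shrinks per-gene residual variances toward a pooled prior estimated by
#' method of moments on `log(s_g^2)` (the digamma/trigamma inversion of the
#' scaled-inverse-chi-square hierarchy): posterior variance
#' `s~_g^2 = (d0*s0^2 + d_g*s_g^2) / (d0 + d_g)`, moderated
#' `t = log2fc / (s~_g * sqrt(v_contrast))` on `d0 + d_g` degrees of
#' freedom. When the observed variances carry no excess dispersion beyond
#' chi-square sampling noise, `d0` is capped at 1e6 ("infinite" pooling, all
#' posterior variances equal `s0^2`).
#'
#' @param fits a `GeneFits` object from [fit_linear_models()].
#' @return A `DiffExprTable` data.frame: `gene`, `log2fc`, `t_mod`,
#'   `p_value`, `fdr`, `sigma2`, `s2_post`, `df_total`; attributes `d0`,
#'   `s0_2`.
#' @export
moderate_ebayes <- function(fits) {
  stopifnot(inherits(fits, "GeneFits"))
  s2 <- fits$sigma2
  dg <- fits$df_resid
  if (length(s2) < 10) stop("need >= 10 genes for moment estimation of the prior")
  d0_cap <- 1e6
  ok <- s2 > 0                     # zero-residual genes excluded from moments
  z <- log(s2[ok])
  e <- z - digamma(dg / 2) + log(dg / 2)
  n_ok <- length(e)
  ebar <- mean(e)
  excess <- mean((e - ebar)^2) * n_ok / (n_ok - 1) - trigamma(dg / 2)
  if (is.na(excess) || excess <= 0) {
    d0 <- d0_cap
  } else {
    d0 <- min(2 * trigamma_inverse(excess), d0_cap)
  }
  if (d0 >= d0_cap) {
    d0 <- d0_cap
    s0_2 <- exp(ebar)              # limit: prior log-variance mean
  } else {
    s0_2 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  }
  s2_post <- if (d0 >= d0_cap) rep(s0_2, length(s2)) else
    (d0 * s0_2 + dg * s2) / (d0 + dg)
  df_total <- d0 + dg
  t_mod <- fits$log2fc / sqrt(s2_post * fits$v_contrast)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- data.frame(gene = fits$gene, log2fc = fits$log2fc, t_mod = t_mod,
                    p_value = p, fdr = bh_adjust(p), sigma2 = s2,
                    s2_post = s2_post, df_total = df_total,
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  class(out) <- c("DiffExprTable", "data.frame")
  out
}

#' Covariate-adjusted moderated differential expression
#'
#' Convenience composition: build the design, fit per-gene OLS, moderate.
#'
#' @inheritParams build_design
#' @param ds an [expression_dataset()].
#' @return A `DiffExprTable`, see [moderate_ebayes()].
#' @export
diff_expression <- function(ds, contrast = "case_vs_control",
                            split_labels = NULL, age_df = 1) {
  design <- build_design(ds$metadata, contrast = contrast,
                         split_labels = split_labels, age_df = age_df)
  moderate_ebayes(fit_linear_models(ds, design))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order
#' (delegates to [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select differentially expressed genes
#'
#' Strict thresholds on both criteria: `fdr < fdr_max` and
#' `|log2fc| > lfc_min` (boundary values excluded).
#'
#' @param table a `DiffExprTable`.
#' @param fdr_max FDR ceiling (default 0.05).
#' @param lfc_min minimum |log2 fold change| (default 0.5).
#' @return character vector of gene symbols.
#' @export
select_degs <- function(table, fdr_max = 0.05, lfc_min = 0.5) {
  stopifnot(fdr_max > 0, lfc_min > 0)
  table$gene[table$fdr < fdr_max & abs(table$log2fc) > lfc_min]
}

#' Intersection of two gene lists
#' @param a,b character vectors.
#' @return sorted character vector of shared genes.
#' @export
overlap_genes <- function(a, b) sort(intersect(a, b))

#' Stack several region datasets into one combined dataset
#'
#' Samples are concatenated on the shared gene universe (intersection of
#' gene sets, in first dataset's order); sample ids are prefixed with the
#' dataset id when duplicated across datasets.
#'
#' @param datasets list of [expression_dataset()] objects.
#' @param dataset_id id for the combined dataset.
#' @return An [expression_dataset()].
#' @export
combine_datasets <- function(datasets, dataset_id = "combined") {
  stopifnot(length(datasets) >= 1)
  genes <- Reduce(intersect, lapply(datasets, `[[`, "genes"))
  if (!length(genes)) stop("datasets share no genes")
  all_ids <- unlist(lapply(datasets, `[[`, "samples"))
  prefix <- anyDuplicated(all_ids) > 0
  vals <- do.call(cbind, lapply(datasets, function(d) {
    m <- d$values[genes, , drop = FALSE]
    if (prefix) colnames(m) <- paste(d$dataset_id, colnames(m), sep = ".")
    m
  }))
  meta <- do.call(rbind, lapply(datasets, function(d) {
    md <- d$metadata
    if (prefix) md$sample_id <- paste(d$dataset_id, md$sample_id, sep = ".")
    md
  }))
  expression_dataset(vals, meta, dataset_id)
}
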