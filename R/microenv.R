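#' ssGSEA marker scores per cell type
#'
#' Scores every sample against each cell type's marker gene set with
#' [ssgsea_score()] — the marker enrichment score used as a relative
#' cell-abundance proxy (e.g. microglia markers for microglial content).
#' Cell types whose marker set shares no gene with the dataset are skipped
#' with a warning.
#'
#' @param ds an [expression_dataset()].
#' @param markers a [gene_set_collection()] of marker sets, one per cell type.
#' @param alpha rank-weighting exponent.
#' @return named list of [sample_score_vector()], one per scored cell type.
#' @export
score_markers <- function(ds, markers, alpha = 0.25) {
  stopifnot(inherits(markers, "GeneSetCollection"))
  present <- vapply(markers$sets, function(g) any(g %in% ds$genes), TRUE)
  if (any(!present))
    warning("marker set(s) with no gene in dataset skipped: ",
            paste(names(markers$sets)[!present], collapse = ", "))
  sets <- markers$sets[present]
  stats::setNames(lapply(names(sets), function(ct)
    ssgsea_score(ds, sets[[ct]], alpha = alpha, score_name = ct)),
    names(sets))
}

#' Non-negative least-squares cell-type deconvolution
#'
#' Estimates per-sample cell-type content by regressing each sample's
#' linear-scale expression (`2^x - 1`, matching the `log2(x + 1)` loading
#' convention) on the signature-matrix columns under non-negativity,
#' restricted to the genes shared between dataset and signature. In
#' `relative` mode coefficients are rescaled to sum to 1 (a degenerate
#' all-zero fit becomes the uniform vector with a warning); `absolute` mode
#' returns the raw coefficients, which scale with overall expression level.
#'
#' @param ds an [expression_dataset()] on the log2 scale.
#' @param sig a [signature_matrix()] (linear scale).
#' @param mode `"relative"` or `"absolute"`.
#' @return An `AbundanceMatrix`: samples x cell types matrix with a `mode`
#'   attribute.
#' @export
nnls_deconvolve <- function(ds, sig, mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ds, "ExpressionDataset"), inherits(sig, "SignatureMatrix"))
  shared <- intersect(ds$genes, sig$genes)
  if (length(shared) < 2) stop("need >= 2 genes shared between dataset and signature")
  a <- sig$values[shared, , drop = FALSE]
  if (qr(a)$rank < ncol(a))
    stop("signature matrix is rank-deficient on the shared genes")
  lin <- 2^ds$values[shared, , drop = FALSE] - 1
  coefs <- vapply(seq_along(ds$samples), function(j)
    pracma::lsqnonneg(a, lin[, j])$x, numeric(ncol(a)))
  ab <- t(coefs)
  dimnames(ab) <- list(ds$samples, sig$cell_types)
  if (mode == "relative") {
    tot <- rowSums(ab)
    zero <- tot == 0
    if (any(zero)) {
      warning(sum(zero), " sample(s) had an all-zero fit; set to uniform proportions")
      ab[zero, ] <- 1 / ncol(ab)
      tot[zero] <- 1
    }
    ab <- ab / tot
  }
  structure(ab, mode = mode, class = c("AbundanceMatrix", class(ab)))
}

#' Two-group comparison with a directed log p-value
#'
#' Two-sided Wilcoxon rank-sum test: exact when the combined sample size is
#' at most 20 and the values are tie-free, otherwise the normal
#' approximation with tie-corrected variance. The directed log p,
#' `sign(median_case - median_control) * (-log10 p)`, is positive when the
#' quantity is higher in cases.
#'
#' @param values numeric vector, one value per sample.
#' @param labels character vector `"control"`/`"case"` parallel to `values`.
#' @return list of class `AssociationResult`: `statistic`, `p_value`,
#'   `directed_log_p`, `rho` (NA), `adjusted` (FALSE).
#' @export
compare_groups <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  x <- values[labels == "case"]
  y <- values[labels == "control"]
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 samples")
  if (length(unique(c(x, y))) == 1) {
    res <- list(statistic = length(x) * length(y) / 2, p_value = 1)
  } else {
    n_tot <- length(x) + length(y)
    exact <- n_tot <= 20 && !any(duplicated(c(x, y)))
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                              exact = exact, correct = !exact))
    res <- list(statistic = unname(wt$statistic), p_value = min(wt$p.value, 1))
  }
  dir <- sign(stats::median(x) - stats::median(y))
  structure(list(statistic = res$statistic, p_value = res$p_value,
                 directed_log_p = dir * -log10(res$p_value),
                 rho = NA_real_, adjusted = FALSE),
            class = "AssociationResult")
}

#' Spearman correlation with t-approximation p-value
#'
#' Rank correlation on average ranks (ties averaged); significance from the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`, two-sided. A
#' perfect monotone relation returns p = 0 by that formula's limit.
#'
#' @param x,y paired numeric vectors, `n >= 4`.
#' @return `AssociationResult` with `rho` filled in.
#' @export
spearman_assoc <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("need n >= 4 pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("constant vector; Spearman correlation undefined")
  rho <- stats::cor(x, y, method = "spearman")
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(statistic = rho, p_value = p,
                 directed_log_p = sign(rho) * -log10(max(p, .Machine$double.xmin)),
                 rho = rho, adjusted = FALSE),
            class = "AssociationResult")
}

#' Covariate-adjusted association
#'
#' Tests whether `x` is associated with `y` after adjusting for covariates,
#' via `y ~ x + covariates`: ordinary least squares for a continuous
#' outcome, logistic regression (iteratively reweighted least squares, max
#' 50 iterations, tolerance 1e-8) for a binary one. Returns the Wald
#' statistic and p-value for the `x` coefficient. Non-convergence or
#' effectively perfect separation in the logistic family is flagged with
#' `p_value = NA`.
#'
#' @param y outcome: numeric, or binary (logical / 0-1 / two-level factor)
#'   for the logistic family.
#' @param x numeric exposure of interest.
#' @param covariates data.frame of covariates (may be NULL or empty).
#' @param family `"linear"` or `"logistic"`.
#' @return `AssociationResult`; `statistic` is the Wald z/t for `x`,
#'   `adjusted = TRUE`.
#' @export
adjusted_assoc <- function(y, x, covariates = NULL, family = c("linear", "logistic")) {
  family <- match.arg(family)
  dat <- data.frame(.y = if (is.factor(y)) as.numeric(y) - 1 else as.numeric(y),
                    .x = x)
  if (!is.null(covariates) && NCOL(covariates) > 0)
    dat <- cbind(dat, as.data.frame(covariates))
  form <- stats::as.formula(paste(".y ~", paste(setdiff(names(dat), ".y"),
                                                collapse = " + ")))
  if (family == "linear") {
    fit <- stats::lm(form, data = dat)
    co <- summary(fit)$coefficients
    stat <- co[".x", "t value"]; p <- co[".x", "Pr(>|t|)"]
    eff <- co[".x", "Estimate"]
  } else {
    fit <- suppressWarnings(stats::glm(form, data = dat, family = stats::binomial(),
                                       control = stats::glm.control(maxit = 50,
                                                                    epsilon = 1e-8)))
    mu <- stats::fitted(fit)
    separated <- !fit$converged || all(mu < 1e-8 | mu > 1 - 1e-8)
    co <- summary(fit)$coefficients
    if (separated) {
      return(structure(list(statistic = NA_real_, p_value = NA_real_,
                            directed_log_p = NA_real_, rho = NA_real_,
                            adjusted = TRUE, separation = TRUE),
                       class = "AssociationResult"))
    }
    stat <- co[".x", "z value"]; p <- co[".x", "Pr(>|z|)"]
    eff <- co[".x", "Estimate"]
  }
  structure(list(statistic = stat, p_value = p,
                 directed_log_p = sign(eff) * -log10(max(p, .Machine$double.xmin)),
                 rho = NA_real_, adjusted = TRUE, separation = FALSE),
            class = "AssociationResult")
}

#' @export
print.AssociationResult <- function(x, ...) {
  cat(sprintf("AssociationResult: statistic = %.4g, p = %.3g, directed log p = %.3g%s\n",
              x$statistic, x$p_value, x$directed_log_p,
              if (isTRUE(x$adjusted)) " (covariate-adjusted)" else ""))
  invisible(x)
}

#' Group-difference and index-association table for cell abundances
#'
#' For every cell type: the case-vs-control Wilcoxon directed log p on its
#' abundance (or marker score), and the Spearman correlation of the
#' abundance with a per-sample index.
#'
#' @param abundances samples x cell types matrix (an `AbundanceMatrix` or
#'   marker-score matrix).
#' @param meta sample metadata with `sample_id` and `group`.
#' @param index optional [sample_score_vector()] to correlate against.
#' @return data.frame: `cell_type`, `statistic`, `p_value`,
#'   `directed_log_p`, `rho`, `rho_p`.
#' @export
microenv_association <- function(abundances, meta, index = NULL) {
  ids <- rownames(abundances)
  grp <- meta$group[match(ids, meta$sample_id)]
  rows <- lapply(colnames(abundances), function(ct) {
    cg <- compare_groups(abundances[, ct], grp)
    rho <- rho_p <- NA_real_
    if (!is.null(index)) {
      sc <- stats::setNames(index$scores, index$sample_ids)[ids]
      sp <- try(spearman_assoc(abundances[, ct], sc), silent = TRUE)
      if (!inherits(sp, "try-error")) { rho <- sp$rho; rho_p <- sp$p_value }
    }
    data.frame(cell_type = ct, statistic = cg$statistic, p_value = cg$p_value,
               directed_log_p = cg$directed_log_p, rho = rho, rho_p = rho_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
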