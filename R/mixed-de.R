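#' Fit the weighted random-intercept model for one gene
#'
#' REML fit of `y = X beta + u_subject + e` with per-observation precision
#' weights, where `X` is the fixed-effect design of [build_design()]. The
#' variance ratio `theta = tau^2 / sigma^2` is profiled out numerically;
#' at `theta = 0` the fit reduces exactly to weighted least squares.
#' Weights are normalized to mean 1 within the gene, so rescaling all
#' weights leaves the fit unchanged.
#'
#' @param y per-sample log2 values (named by sample or ordered as `meta`).
#' @param w per-sample positive weights (default all 1).
#' @param meta sample metadata (needs `subject_id`, `diagnosis`).
#' @param spec a [model_spec()].
#' @return a list (`gene_fit`): `beta` (named fixed effects; `diagnosisAD`
#'   is the log2 fold change), `se_unit` (unscaled standard errors,
#'   se / sigma-hat), `sigma2`, `tau2`, `df_resid` (see [fit_all()] for
#'   the df convention), `converged`.
#' @export
fit_gene_lmm <- function(y, w = NULL, meta, spec = model_spec()) {
  n <- length(y)
  if (n != nrow(meta)) stopf("length(y) != nrow(meta)")
  if (is.null(w)) w <- rep(1, n)
  if (length(w) != n || any(w <= 0)) stopf("weights must be positive, one per sample")
  per_group <- tapply(meta$subject_id, meta$diagnosis, function(s) length(unique(s)))
  if (any(per_group < 2)) stopf("need >= 2 subjects per diagnosis group")
  fit <- fit_all(matrix(y, 1, n, dimnames = list("g", meta$sample_id)),
    matrix(w, 1, n, dimnames = list("g", meta$sample_id)),
    meta = meta, spec = spec
  )
  bcols <- grep("^beta\\.", names(fit))
  beta <- unlist(fit[1, bcols])
  names(beta) <- sub("^beta\\.", "", names(fit)[bcols])
  list(
    beta = beta, se_unit = fit$se_unit[1], sigma2 = fit$sigma2[1],
    tau2 = fit$tau2[1], df_resid = fit$df_resid[1],
    converged = fit$converged[1]
  )
}

#' Fit the mixed model for every gene
#'
#' Runs the per-gene weighted REML fit across the whole matrix. Degenerate
#' genes (zero residual variance in an unweighted screen) are retained with
#' `converged = FALSE` and NA statistics, never dropped.
#'
#' The degrees of freedom attached to each gene (used downstream for
#' variance moderation and the moderated-t reference distribution) follow
#' the `df_method` convention. The disease contrast is a between-subject
#' comparison, so its effective degrees of freedom are governed by the
#' number of subjects, not the number of samples: the default
#' `"between_within"` uses `n_subjects - p_between`, where `p_between`
#' counts the fixed effects constant within subject (intercept and
#' diagnosis). `"residual"` uses `n_samples - p - 1` (observations minus
#' fixed effects minus one for the variance component), which overstates
#' the information about a between-subject contrast and inflates the far
#' tail of its null distribution.
#'
#' @param E_adj genes x samples log2-scale matrix (covariate-adjusted).
#' @param W genes x samples positive weight matrix (or NULL for unweighted).
#' @param meta sample metadata.
#' @param spec a [model_spec()].
#' @param df_method `"between_within"` (default) or `"residual"`; see
#'   Details.
#' @return data.frame with one row per gene: `gene_id`, `logFC`
#'   (diagnosis AD vs control), `AvExp`, per-coefficient `beta.*`,
#'   `se_unit` (of the diagnosis contrast), `sigma2`, `tau2`, `df_resid`,
#'   `converged`.
#' @export
fit_all <- function(E_adj, W = NULL, meta, spec = model_spec(),
                    df_method = c("between_within", "residual")) {
  df_method <- match.arg(df_method)
  check_expression_matrix(E_adj)
  meta <- align_meta(E_adj, meta)
  if (is.null(W)) W <- matrix(1, nrow(E_adj), ncol(E_adj))
  if (!all(dim(W) == dim(E_adj))) stopf("weight matrix shape mismatch")
  if (any(!is.finite(W)) || any(W <= 0)) stopf("weights must be positive and finite")
  X <- build_design(meta, spec)
  group <- match(meta$subject_id, unique(meta$subject_id)) - 1L

  # screen degenerate genes (constant within fitted groups)
  row_var <- apply(E_adj, 1, var)
  usable <- row_var > 1e-18

  res <- .reml_fit_matrix(
    E_adj[usable, , drop = FALSE], X,
    W[usable, , drop = FALSE], group
  )

  G <- nrow(E_adj)
  p <- ncol(X)
  beta <- matrix(NA_real_, G, p, dimnames = list(rownames(E_adj), colnames(X)))
  se_unit_all <- matrix(NA_real_, G, p)
  sigma2 <- tau2 <- rep(NA_real_, G)
  converged <- rep(FALSE, G)
  beta[usable, ] <- res$beta
  se_unit_all[usable, ] <- res$se_unit
  sigma2[usable] <- res$sigma2
  tau2[usable] <- res$tau2
  converged[usable] <- res$converged

  df_resid <- if (df_method == "between_within") {
    q <- length(unique(meta$subject_id))
    # fixed effects constant within subject (intercept, diagnosis, ...)
    p_between <- sum(vapply(seq_len(p), function(j) {
      all(tapply(X[, j], meta$subject_id, function(v) length(unique(v))) == 1)
    }, logical(1)))
    max(q - p_between, 1L)
  } else {
    res$df_resid
  }

  out <- data.frame(
    gene_id = rownames(E_adj),
    logFC = beta[, "diagnosisAD"],
    AvExp = rowMeans(E_adj),
    se_unit = se_unit_all[, which(colnames(X) == "diagnosisAD")],
    sigma2 = sigma2,
    tau2 = tau2,
    df_resid = df_resid,
    converged = converged,
    stringsAsFactors = FALSE
  )
  for (j in seq_len(p)) out[[paste0("beta.", colnames(X)[j])]] <- beta[, j]
  rownames(out) <- NULL
  out
}

#' Bonferroni family-wise correction
#'
#' @param p_raw raw p-values in `[0, 1]` (NAs pass through).
#' @param m number of tests (defaults to `length(p_raw)`; non-converged
#'   genes with NA p still count toward `m` when supplied by the caller).
#' @return `pmin(1, m * p_raw)`.
#' @export
bonferroni <- function(p_raw, m = length(p_raw)) {
  if (m < 1) stopf("m must be >= 1")
  ok <- !is.na(p_raw)
  if (any(p_raw[ok] < 0 | p_raw[ok] > 1)) stopf("p-values must be in [0, 1]")
  pmin(1, m * p_raw)
}

#' Wilcoxon rank-sum test of AD vs control within one region
#'
#' Single-region, per-observation comparison that deliberately ignores the
#' subject hierarchy (each subject contributes at most one sample per
#' region, so independence holds within a region). Uses the exact rank-sum
#' distribution when the combined sample size is at most 20 and there are
#' no ties, and the normal approximation with tie correction otherwise.
#'
#' @param E_log genes x samples log2-scale matrix.
#' @param meta sample metadata.
#' @param region region label to test within.
#' @return named vector of two-sided p-values, one per gene.
#' @export
wilcoxon_region <- function(E_log, meta, region) {
  check_expression_matrix(E_log)
  meta <- align_meta(E_log, meta)
  if (!region %in% meta$region) stopf("region '%s' absent from metadata", region)
  in_region <- meta$region == region
  ad <- in_region & meta$diagnosis == "AD"
  ctrl <- in_region & meta$diagnosis == "control"
  if (sum(ad) < 2 || sum(ctrl) < 2) {
    stopf("need >= 2 samples per group in region '%s'", region)
  }
  exact <- (sum(ad) + sum(ctrl)) <= 20
  apply(E_log, 1, function(y) {
    p <- suppressWarnings(
      wilcox.test(y[ad], y[ctrl], exact = exact, correct = TRUE)$p.value
    )
    if (!is.finite(p)) 1 else p # fully tied data carries no evidence
  })
}

#' Per-observation OLS t-test ignoring the subject hierarchy
#'
#' The anti-pattern the mixed model exists to avoid: treats all samples as
#' independent and tests the diagnosis coefficient by ordinary least
#' squares. Provided for calibration comparisons (its type-I error exceeds
#' the mixed model's whenever the subject variance is positive).
#'
#' @param E_log genes x samples log2-scale matrix.
#' @param meta sample metadata.
#' @param spec a [model_spec()].
#' @return data.frame `gene_id, logFC, t, p`.
#' @export
ols_naive_de <- function(E_log, meta, spec = model_spec()) {
  check_expression_matrix(E_log)
  meta <- align_meta(E_log, meta)
  X <- build_design(meta, spec)
  qr_x <- qr(X)
  n <- ncol(E_log)
  p <- ncol(X)
  coefs <- t(qr.coef(qr_x, t(E_log)))
  fitted <- t(qr.fitted(qr_x, t(E_log)))
  rss <- rowSums((E_log - fitted)^2)
  sigma2 <- rss / (n - p)
  xtx_inv <- chol2inv(qr.R(qr_x))
  j <- which(colnames(X) == "diagnosisAD")
  se <- sqrt(sigma2 * xtx_inv[j, j])
  tstat <- coefs[, j] / se
  data.frame(
    gene_id = rownames(E_log), logFC = coefs[, j], t = tstat,
    p = 2 * pt(-abs(tstat), df = n - p),
    stringsAsFactors = FALSE
  )
}
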