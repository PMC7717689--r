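#' Log2-transform an FPKM-scale expression matrix
#'
#' Applies `value -> log2(value + offset)` elementwise. The offset (default
#' 1) keeps zero FPKM at log2 value 0 and damps the unequal variability of
#' large versus small values.
#'
#' @param E non-negative expression matrix.
#' @param offset positive pseudo-value added before taking log2.
#' @return matrix of the same shape on the log2 scale.
#' @seealso [unlog_transform()] for the inverse.
#' @export
log_transform <- function(E, offset = 1) {
  if (offset <= 0) stopf("offset must be positive")
  check_expression_matrix(E)
  if (any(E + offset <= 0)) stopf("value + offset <= 0; cannot take log2")
  log2(E + offset)
}

#' Invert [log_transform()]
#'
#' @param E_log log2-scale matrix.
#' @param offset the offset used in the forward transform.
#' @return FPKM-scale matrix `2^E_log - offset`.
#' @export
unlog_transform <- function(E_log, offset = 1) {
  2^E_log - offset
}

#' Regress nuisance covariates out of a log-scale expression matrix
#'
#' For each gene, fits ordinary least squares of expression on the given
#' metadata covariates (with intercept) and returns residuals plus the gene
#' grand mean, so average expression is preserved while each gene's values
#' are made orthogonal to the covariates. `sex` is encoded female = 1,
#' male = 0 (any consistent coding gives identical residuals). The operation
#' is idempotent.
#'
#' The group contrast of interest must not be adjusted away: `diagnosis`
#' is rejected as a covariate.
#'
#' @param E_log genes x samples log2-scale matrix.
#' @param meta sample metadata (rows matched to columns of `E_log` by
#'   `sample_id`).
#' @param covariates character vector of metadata column names
#'   (default `c("age", "sex")`).
#' @return adjusted matrix, same shape and dimnames.
#' @export
adjust_covariates <- function(E_log, meta, covariates = c("age", "sex")) {
  check_expression_matrix(E_log)
  meta <- align_meta(E_log, meta)
  if (length(covariates) == 0) {
    return(E_log)
  }
  if ("diagnosis" %in% covariates) {
    stopf("'diagnosis' is the contrast of interest and cannot be adjusted out")
  }
  missing <- setdiff(covariates, names(meta))
  if (length(missing)) {
    stopf("covariate column(s) not in metadata: %s", paste(missing, collapse = ", "))
  }
  X <- cbind(`(Intercept)` = 1)
  X <- matrix(1, nrow(meta), 1, dimnames = list(NULL, "(Intercept)"))
  for (cv in covariates) {
    v <- meta[[cv]]
    v <- if (cv == "sex") encode_sex(v) else as.numeric(v)
    if (anyNA(v)) stopf("covariate '%s' is not numeric-encodable", cv)
    if (sd(v) == 0) stopf("covariate '%s' is constant (singular design)", cv)
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stopf("covariate design is singular")
  # residuals + per-gene grand mean, computed for all genes at once
  fitted <- t(qr.fitted(qr_x, t(E_log)))
  res <- E_log - fitted
  res + rowMeans(E_log)
}
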