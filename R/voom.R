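#' Unweighted first-pass fit feeding the mean-variance trend
#'
#' Fits, per gene, ordinary least squares with the same fixed-effect
#' structure as the downstream mixed model (subjects pooled, no weights),
#' and extracts the ingredients of the mean-variance trend: average log2
#' expression, the square root of the residual standard deviation, and
#' per-observation fitted values. Genes with zero residual degrees of
#' freedom or zero residual variance are flagged and excluded from trend
#' fitting.
#'
#' @param E_log genes x samples log2-scale matrix (after covariate
#'   adjustment).
#' @param meta sample metadata.
#' @param spec a [model_spec()].
#' @return list with `avexp` (row means), `sqrt_sd` (residual sd^(1/2) per
#'   gene; NA for flagged genes), `fitted` (genes x samples matrix),
#'   `sigma` (residual sd), `df_resid`, and logical `flagged`.
#' @export
first_pass_fit <- function(E_log, meta, spec = model_spec()) {
  check_expression_matrix(E_log)
  meta <- align_meta(E_log, meta)
  X <- build_design(meta, spec)
  n <- ncol(E_log)
  p <- ncol(X)
  df <- n - p
  if (df <= 0) stopf("no residual degrees of freedom (n <= p)")
  qr_x <- qr(X)
  fitted <- t(qr.fitted(qr_x, t(E_log)))
  dimnames(fitted) <- dimnames(E_log)
  res <- E_log - fitted
  sigma <- sqrt(rowSums(res^2) / df)
  flagged <- sigma < 1e-10
  sqrt_sd <- sqrt(sigma)
  sqrt_sd[flagged] <- NA_real_
  list(
    avexp = rowMeans(E_log), sqrt_sd = sqrt_sd, fitted = fitted,
    sigma = sigma, df_resid = df, flagged = flagged
  )
}

#' Fit the LOWESS mean-variance trend
#'
#' Robust locally weighted regression of per-gene sqrt residual sd on
#' average log2 expression. The returned trend interpolates linearly
#' between the fitted points and clamps to the boundary value outside
#' the observed range.
#'
#' @param avexp per-gene mean log2 expression.
#' @param sqrt_sd per-gene square-root residual standard deviation (NAs
#'   dropped).
#' @param span LOWESS span in (0, 1].
#' @param iterations robustness iterations.
#' @return an object of class `trend_fit` with fields `knots_x`, `knots_y`,
#'   `span`. Evaluate with [predict_trend()].
#' @export
lowess_trend <- function(avexp, sqrt_sd, span = 0.5, iterations = 3) {
  if (span <= 0 || span > 1) stopf("span must be in (0, 1]")
  ok <- is.finite(avexp) & is.finite(sqrt_sd)
  if (sum(ok) < 50) stopf("need >= 50 genes to fit the mean-variance trend")
  x <- avexp[ok]
  y <- sqrt_sd[ok]
  if (diff(range(x)) == 0) stopf("all mean expressions identical; no trend estimable")
  fit <- lowess(x, y, f = span, iter = iterations)
  # collapse duplicate x (lowess returns sorted x) and floor at small positive
  knots_x <- unique(fit$x)
  knots_y <- vapply(knots_x, function(v) mean(fit$y[fit$x == v]), numeric(1))
  knots_y <- pmax(knots_y, 1e-6)
  structure(list(knots_x = knots_x, knots_y = knots_y, span = span),
    class = "trend_fit"
  )
}

#' Evaluate a fitted mean-variance trend
#'
#' Linear interpolation between knots; values outside the knot range clamp
#' to the boundary fitted value.
#'
#' @param trend a `trend_fit` from [lowess_trend()].
#' @param x mean log2 expression values (vector or matrix).
#' @return predicted sqrt-sd values, same shape as `x`.
#' @export
predict_trend <- function(trend, x) {
  if (!inherits(trend, "trend_fit")) stopf("trend must be a trend_fit")
  out <- approx(trend$knots_x, trend$knots_y,
    xout = as.vector(x), rule = 2
  )$y
  if (is.matrix(x)) out <- matrix(out, nrow(x), ncol(x), dimnames = dimnames(x))
  out
}

#' Convert the mean-variance trend into precision weights
#'
#' The trend predicts the square root of the residual standard deviation at
#' each observation's fitted value, so the predicted variance is
#' `trend(fitted)^4` and the precision weight is its inverse:
#' `w = trend(fitted)^(-4)`.
#'
#' @param fitted genes x samples matrix of first-pass fitted values.
#' @param trend a `trend_fit`.
#' @return positive weight matrix of the same shape.
#' @export
compute_weights <- function(fitted, trend) {
  if (any(!is.finite(fitted))) stopf("non-finite fitted value")
  predict_trend(trend, fitted)^(-4)
}

#' One-call voom-style weight computation
#'
#' Runs [first_pass_fit()], [lowess_trend()] and [compute_weights()].
#' Genes flagged as degenerate in the first pass receive weight 1
#' everywhere and carry a QC flag.
#'
#' @inheritParams first_pass_fit
#' @param span,iterations LOWESS parameters.
#' @return list with `weights` (genes x samples), `trend` (`trend_fit`),
#'   `first_pass`, and logical `flagged` per gene.
#' @export
voom_weights <- function(E_log, meta, spec = model_spec(), span = 0.5,
                         iterations = 3) {
  fp <- first_pass_fit(E_log, meta, spec)
  trend <- lowess_trend(fp$avexp, fp$sqrt_sd, span = span, iterations = iterations)
  W <- compute_weights(fp$fitted, trend)
  if (any(fp$flagged)) W[fp$flagged, ] <- 1
  list(weights = W, trend = trend, first_pass = fp, flagged = fp$flagged)
}

#' QC plot of the mean-variance trend
#'
#' Scatter of per-gene sqrt residual sd against average log2 expression with
#' the fitted LOWESS trend overlaid, written to a PNG file.
#'
#' @param fp output of [first_pass_fit()].
#' @param trend a `trend_fit`.
#' @param path output PNG path.
#' @return invisibly, `path`.
#' @export
plot_trend <- function(fp, trend, path) {
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  ok <- !fp$flagged
  plot(fp$avexp[ok], fp$sqrt_sd[ok],
    pch = 16, cex = 0.4, col = "grey40",
    xlab = "average log2 expression", ylab = "sqrt(residual sd)",
    main = "mean-variance trend"
  )
  xs <- seq(min(fp$avexp[ok]), max(fp$avexp[ok]), length.out = 200)
  graphics::lines(xs, predict_trend(trend, xs), col = "red", lwd = 2)
  invisible(path)
}
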