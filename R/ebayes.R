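#' Invert the trigamma function
#'
#' Newton iteration on `trigamma(y) = x`, used by the method-of-moments
#' fit of the variance prior.
#'
#' @param x positive value.
#' @return `y` with `trigamma(y) = x`.
#' @keywords internal
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) stopf("trigamma_inverse needs a positive value")
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Fit the scaled inverse chi-square prior for gene-wise variances
#'
#' Method-of-moments estimation of the prior degrees of freedom `d0` and
#' prior variance `s0^2` from observed gene-wise residual variances `s^2`
#' with residual df `d`, matching the first two moments of `log(s^2)`
#' through digamma/trigamma identities. A non-positive moment estimate of
#' `trigamma(d0/2)` yields `d0 = Inf` (complete shrinkage to the common
#' variance).
#'
#' @param s2 gene-wise variances.
#' @param df residual degrees of freedom (scalar or per gene).
#' @return list `d0`, `s0_2`.
#' @export
fit_variance_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & is.finite(df) & df > 0
  if (sum(ok) < 2) stopf("need >= 2 positive finite variances")
  z <- log(s2[ok])
  d <- df[ok]
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  if (var(z) == 0) {
    # degenerate spread: no information about d0; shrink completely to the
    # common observed variance
    return(list(d0 = Inf, s0_2 = exp(z[1])))
  }
  evar <- sum((e - emean)^2) / (length(e) - 1) - mean(trigamma(d / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(emean)
  }
  list(d0 = d0, s0_2 = s0_2)
}

#' Empirical-Bayes moderation of gene-wise variances
#'
#' Squeezes each gene's residual variance toward the common prior variance,
#' `s~^2 = (d0 s0^2 + d s^2) / (d0 + d)`, and forms the moderated
#' t-statistic `t~ = logFC / (s~ * se_unit)` with `d0 + d` degrees of
#' freedom, plus two-sided p-values. Genes that did not converge keep NA
#' statistics but are preserved in the output.
#'
#' @param fits per-gene fit table from [fit_all()].
#' @return list of class `moderation_result`: `d0`, `s0_2`, and a
#'   data.frame `table` with `gene_id, logFC, AvExp, t, P.Value, df_total,
#'   s_tilde2, se_unit, converged, tau2`.
#' @export
ebayes_moderate <- function(fits) {
  ok <- fits$converged & is.finite(fits$sigma2) & fits$sigma2 > 0
  if (sum(ok) < 20) stopf("need >= 20 genes with finite variances to moderate")
  prior <- fit_variance_prior(fits$sigma2[ok], fits$df_resid[ok])
  d0 <- prior$d0
  s0_2 <- prior$s0_2
  d <- fits$df_resid
  s_tilde2 <- if (is.infinite(d0)) {
    rep(s0_2, nrow(fits))
  } else {
    (d0 * s0_2 + d * fits$sigma2) / (d0 + d)
  }
  s_tilde2[!ok] <- NA_real_
  df_total <- ifelse(ok, d0 + d, NA_real_)
  tmod <- fits$logFC / (sqrt(s_tilde2) * fits$se_unit)
  pval <- 2 * pt(-abs(tmod), df = pmin(df_total, 1e100))
  structure(
    list(
      d0 = d0, s0_2 = s0_2,
      table = data.frame(
        gene_id = fits$gene_id, logFC = fits$logFC, AvExp = fits$AvExp,
        t = tmod, P.Value = pval, df_total = df_total,
        s_tilde2 = s_tilde2, se_unit = fits$se_unit,
        converged = fits$converged, tau2 = fits$tau2,
        stringsAsFactors = FALSE
      )
    ),
    class = "moderation_result"
  )
}

# estimate the prior variance v0 of the non-null coefficient distribution
# from the upper tail of the moderated t-statistics (top prior_prob/2
# fraction), following the two-component mixture calibration of the
# moderated-t framework.
estimate_v0 <- function(tstat, se_unit, df_total, prior_prob) {
  ok <- is.finite(tstat) & is.finite(se_unit) & is.finite(df_total)
  tstat <- tstat[ok]
  se_unit <- se_unit[ok]
  df <- pmin(df_total[ok], 1e6)
  ngenes <- length(tstat)
  ntarget <- ceiling(prior_prob / 2 * ngenes)
  if (ntarget < 1) {
    return(NA_real_)
  }
  p <- max(ntarget / ngenes, prior_prob)
  at <- abs(tstat)
  max_df <- max(df)
  i <- df < max_df
  if (any(i)) { # put all statistics on a common-df scale through tail areas
    tail_p <- pt(at[i], df = df[i], lower.tail = FALSE, log.p = TRUE)
    at[i] <- qt(tail_p, df = max_df, lower.tail = FALSE, log.p = TRUE)
  }
  o <- order(at, decreasing = TRUE)[seq_len(ntarget)]
  at_top <- at[o]
  v1 <- se_unit[o]^2
  r <- seq_len(ntarget)
  p0 <- 2 * pt(-at_top, df = max_df)
  ptarget <- ((r - 0.5) / ngenes - (1 - p) * p0) / p
  v0 <- rep(0, ntarget)
  pos <- ptarget > p0
  if (any(pos)) {
    qtarget <- qt(ptarget[pos] / 2, df = max_df, lower.tail = FALSE)
    v0[pos] <- v1[pos] * ((at_top[pos] / qtarget)^2 - 1)
  }
  mean(pmax(v0, 0))
}

#' Posterior log-odds (B-statistic) of differential expression
#'
#' Under a two-component model in which a proportion `prior_prob` of genes
#' is differentially expressed with prior coefficient variance `v0` (on the
#' unscaled-se scale), the posterior log-odds for a gene with moderated
#' statistic `t`, total df `df` and unscaled se `u` is
#' \deqn{B = \log\frac{p}{1-p} - \frac{1}{2}\log r +
#'   \frac{1+df}{2}\log\frac{t^2 + df}{t^2/r + df}, \quad
#'   r = (u^2 + v_0)/u^2.}
#' B is strictly increasing in `|t|` at fixed df and se.
#'
#' @param t_mod moderated t-statistics.
#' @param df_total total degrees of freedom per gene.
#' @param se_unit unscaled standard errors per gene.
#' @param prior_prob prior probability of differential expression.
#' @param v0 prior variance of the standardized effect; estimated from the
#'   upper tail of `t_mod` when NULL.
#' @return numeric vector of posterior log-odds.
#' @export
b_statistic <- function(t_mod, df_total, se_unit, prior_prob = 0.01,
                        v0 = NULL) {
  if (prior_prob <= 0 || prior_prob >= 1) stopf("prior_prob must be in (0, 1)")
  if (is.null(v0)) {
    v0 <- estimate_v0(t_mod, se_unit, df_total, prior_prob)
    if (!is.finite(v0)) v0 <- 0
  }
  if (v0 < 0) stopf("v0 must be non-negative")
  r <- (se_unit^2 + v0) / se_unit^2
  t2 <- t_mod^2
  df <- df_total
  kernel <- ifelse(is.infinite(df) | df > 1e6,
    t2 * (1 - 1 / r) / 2,
    (1 + df) / 2 * log((t2 + df) / (t2 / r + df))
  )
  log(prior_prob / (1 - prior_prob)) - log(r) / 2 + kernel
}

#' Assemble the differential-expression results table
#'
#' Combines the mixed-model fits, empirical-Bayes moderation, Bonferroni
#' correction over all `m` genes (non-converged genes keep NA p-values but
#' still count toward `m`), and the B-statistic, sorted by raw p-value.
#'
#' @param fits per-gene fit table from [fit_all()].
#' @param prior_prob,v0 passed to [b_statistic()].
#' @return data.frame with columns `gene_id, logFC, AvExp, t, P.Value,
#'   adj.P.Val, B, converged, tau2`, plus attributes `d0`, `s0_2`.
#' @export
de_results <- function(fits, prior_prob = 0.01, v0 = NULL) {
  mod <- ebayes_moderate(fits)
  tab <- mod$table
  tab$adj.P.Val <- bonferroni(tab$P.Value, m = nrow(tab))
  tab$B <- b_statistic(tab$t, tab$df_total, tab$se_unit,
    prior_prob = prior_prob, v0 = v0
  )
  out <- tab[order(tab$P.Value), c(
    "gene_id", "logFC", "AvExp", "t", "P.Value", "adj.P.Val", "B",
    "converged", "tau2"
  )]
  rownames(out) <- NULL
  attr(out, "d0") <- mod$d0
  attr(out, "s0_2") <- mod$s0_2
  out
}
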