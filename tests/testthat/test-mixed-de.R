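test_that("with one sample per subject and equal weights the fit is two-sample OLS", {
  meta <- tiny_meta(n_case = 5, n_control = 5, regions = "HIP")
  set.seed(3)
  y <- rnorm(10, 5, 1) + 2 * (meta$diagnosis == "AD")
  fit <- fit_gene_lmm(y, w = rep(1, 10), meta = meta)
  diff_means <- mean(y[meta$diagnosis == "AD"]) - mean(y[meta$diagnosis == "control"])
  expect_equal(unname(fit$beta["diagnosisAD"]), diff_means, tolerance = 1e-10)
})

test_that("the fit is invariant to rescaling all of a gene's weights", {
  meta <- tiny_meta(n_case = 4, n_control = 4)
  set.seed(4)
  u <- rnorm(8, 0, 0.5)
  y <- 3 + 0.5 * (meta$diagnosis == "AD") +
    u[match(meta$subject_id, unique(meta$subject_id))] +
    rnorm(nrow(meta), 0, 0.4)
  w <- runif(nrow(meta), 0.3, 3)
  f1 <- fit_gene_lmm(y, w, meta)
  f2 <- fit_gene_lmm(y, 2 * w, meta)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-9)
  expect_equal(f1$tau2, f2$tau2, tolerance = 1e-8)
  expect_equal(f1$sigma2, f2$sigma2, tolerance = 1e-8)
})

test_that("REML estimates agree with lme4 on weighted multi-region data", {
  skip_if_not_installed("lme4")
  meta <- generate_metadata(cohort_design(), seed = 13)
  set.seed(13)
  subj <- match(meta$subject_id, unique(meta$subject_id))
  for (rep in 1:3) {
    u <- rnorm(45, 0, 0.5)
    y <- 2 + 0.4 * (meta$diagnosis == "AD") + u[subj] + rnorm(nrow(meta), 0, 0.5)
    w <- runif(nrow(meta), 0.5, 2)
    w <- w / mean(w)
    mine <- fit_gene_lmm(y, w, meta)
    ref <- lme4::lmer(
      y ~ dx + (1 | s),
      data = data.frame(y = y, dx = as.numeric(meta$diagnosis == "AD"), s = meta$subject_id),
      weights = w, REML = TRUE
    )
    expect_equal(unname(mine$beta), unname(lme4::fixef(ref)), tolerance = 1e-5)
    expect_equal(mine$tau2, as.numeric(lme4::VarCorr(ref)$s), tolerance = 1e-4)
    expect_equal(mine$sigma2, stats::sigma(ref)^2, tolerance = 1e-4)
  }
})

test_that("REML recovers the subject variance on average", {
  meta <- generate_metadata(cohort_design(missing_rate = 0), seed = 21)
  subj <- match(meta$subject_id, unique(meta$subject_id))
  n <- nrow(meta)
  set.seed(21)
  Y <- t(vapply(1:500, function(i) {
    rnorm(45, 0, 0.5)[subj] + rnorm(n, 0, 0.5)
  }, numeric(n)))
  rownames(Y) <- paste0("G", 1:500)
  colnames(Y) <- meta$sample_id
  fits <- fit_all(Y + 5, NULL, meta)
  expect_equal(mean(fits$tau2), 0.25, tolerance = 0.10)
  expect_equal(mean(fits$sigma2), 0.25, tolerance = 0.05)
})

test_that("fit_all keeps every gene and is deterministic", {
  meta <- tiny_meta(n_case = 5, n_control = 5)
  E <- tiny_matrix(paste0("G", 1:100), meta$sample_id, seed = 5)
  E["G50", ] <- 1 # constant gene
  f1 <- fit_all(E, NULL, meta)
  f2 <- fit_all(E, NULL, meta)
  expect_identical(f1, f2)
  expect_equal(nrow(f1), 100)
  expect_false(f1$converged[f1$gene_id == "G50"])
  expect_true(all(f1$converged[f1$gene_id != "G50"]))
})

test_that("variance prior is recovered from simulated gene-wise variances", {
  set.seed(31)
  d0 <- 4
  s0 <- 0.25
  d <- 20
  sg2 <- d0 * s0 / rchisq(5000, d0)
  s2 <- sg2 * rchisq(5000, d) / d
  pr <- fit_variance_prior(s2, d)
  expect_equal(pr$d0, d0, tolerance = 0.15)
  expect_equal(pr$s0_2, s0, tolerance = 0.05)
})

test_that("moderation matches limma's squeezeVar and eBayes machinery", {
  skip_if_not_installed("limma")
  meta <- generate_metadata(cohort_design(), seed = 17)
  sim <- simulate_expression(meta, simulation_params(n_genes = 300, de_fraction = 0.1), seed = 17)
  E_adj <- adjust_covariates(log_transform(sim$expression), meta)
  fits <- fit_all(E_adj, NULL, meta)
  mod <- ebayes_moderate(fits)
  sq <- limma::squeezeVar(fits$sigma2[fits$converged], fits$df_resid[fits$converged])
  expect_equal(mod$d0, sq$df.prior, tolerance = 1e-8)
  expect_equal(mod$s0_2, sq$var.prior, tolerance = 1e-8)
  expect_equal(
    mod$table$s_tilde2[fits$converged], sq$var.post,
    tolerance = 1e-8
  )

  # full moderated t / p / B against limma's eBayes on the same fits
  ok <- fits$converged
  mal <- new("MArrayLM", list(
    coefficients = matrix(fits$logFC[ok]),
    stdev.unscaled = matrix(fits$se_unit[ok]),
    sigma = sqrt(fits$sigma2[ok]),
    df.residual = fits$df_resid[ok]
  ))
  eb <- limma::eBayes(mal, proportion = 0.01)
  mod_ok <- mod$table[ok, ]
  expect_equal(mod_ok$t, drop(eb$t), tolerance = 1e-8)
  expect_equal(mod_ok$P.Value, drop(eb$p.value), tolerance = 1e-8)
  B <- b_statistic(mod_ok$t, mod_ok$df_total, mod_ok$se_unit, prior_prob = 0.01)
  expect_equal(B, drop(eb$lods), tolerance = 1e-6)
})

test_that("moderation fixed points and limits hold", {
  fits <- data.frame(
    gene_id = paste0("G", 1:30), logFC = rep(c(1, -1), 15),
    AvExp = 5, se_unit = 0.2, sigma2 = 0.5, tau2 = 0.1,
    df_resid = 10, converged = TRUE
  )
  mod <- ebayes_moderate(fits)
  # equal variances: posterior equals the common value for every gene
  expect_true(all(abs(mod$table$s_tilde2 - 0.5) < 1e-8))
  # d0 -> Inf limit: everything shrunk fully to s0
  expect_true(is.infinite(mod$d0))
})

test_that("the B-statistic is symmetric and monotone in |t|", {
  set.seed(41)
  tstat <- c(0, rnorm(200, 0, 3))
  df <- rep(30, 201)
  se <- rep(0.25, 201)
  B <- b_statistic(tstat, df, se, prior_prob = 0.01, v0 = 0.5)
  expect_equal(which.min(B), 1) # t = 0 has the smallest posterior odds
  expect_equal(B[order(abs(tstat))], sort(B), tolerance = 1e-12)
  # equal inputs give equal B
  expect_equal(
    b_statistic(c(2, -2), c(30, 30), c(0.25, 0.25), v0 = 0.5)[1],
    b_statistic(c(2, -2), c(30, 30), c(0.25, 0.25), v0 = 0.5)[2]
  )
})

test_that("Bonferroni correction is exact arithmetic", {
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(1e-6, 50281), 0.050281)
  expect_equal(bonferroni(0, 100), 0)
  p <- runif(20)
  expect_true(all(bonferroni(p, 20) >= p))
  expect_error(bonferroni(1.2, 5), "0, 1")
})

test_that("the region-wise Wilcoxon test matches the exact distribution", {
  meta <- tiny_meta(n_case = 3, n_control = 3, regions = "HIP")
  E <- matrix(c(4, 5, 6, 1, 2, 3), 1,
    dimnames = list("G1", meta$sample_id)
  )
  p <- wilcoxon_region(E, meta, "HIP")
  expect_equal(unname(p), 0.1) # 2 * (1 / C(6,3)) = 0.1 by enumeration

  # ties: identical pooled values give p = 1
  E2 <- matrix(5, 1, 6, dimnames = list("G1", meta$sample_id))
  expect_equal(unname(wilcoxon_region(E2, meta, "HIP")), 1)

  # invariance under strictly monotone transforms
  E3 <- matrix(c(1, 3, 9, 2, 8, 4), 1, dimnames = list("G1", meta$sample_id))
  expect_equal(
    wilcoxon_region(E3, meta, "HIP"),
    wilcoxon_region(2^E3, meta, "HIP")
  )
  expect_error(wilcoxon_region(E, meta, "FWM"), "absent")
})

test_that("ignoring subjects inflates the naive OLS type-I error", {
  meta <- generate_metadata(cohort_design(), seed = 23)
  sim <- simulate_expression(
    meta, simulation_params(n_genes = 1000, de_fraction = 0),
    seed = 23
  )
  E_adj <- adjust_covariates(log_transform(sim$expression), meta)
  naive <- ols_naive_de(E_adj, meta)
  de <- de_results(fit_all(E_adj, NULL, meta))
  expect_gt(mean(naive$p < 0.05), mean(de$P.Value < 0.05, na.rm = TRUE))
  expect_gt(mean(naive$p < 0.05), 0.065)
})
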