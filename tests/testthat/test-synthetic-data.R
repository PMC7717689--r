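test_that("metadata generation respects the design and is deterministic", {
  d <- cohort_design()
  m1 <- generate_metadata(d, seed = 11)
  m2 <- generate_metadata(d, seed = 11)
  expect_identical(m1, m2)
  expect_false(identical(m1, generate_metadata(d, seed = 12)))

  # diagnosis constant within subject; every subject retained
  by_subj <- tapply(m1$diagnosis, m1$subject_id, function(x) length(unique(x)))
  expect_true(all(by_subj == 1))
  expect_equal(length(unique(m1$subject_id)), 45)
  expect_true(all(m1$age >= 60))
  expect_true(all(m1$region %in% d$regions))

  # no missingness: full grid
  full <- generate_metadata(cohort_design(missing_rate = 0), seed = 1)
  expect_equal(nrow(full), 45 * 4)
})

test_that("default missingness yields about 165 samples on average", {
  ns <- vapply(1:40, function(s) {
    nrow(generate_metadata(cohort_design(), seed = s))
  }, numeric(1))
  expect_gt(mean(ns), 160)
  expect_lt(mean(ns), 170)
})

test_that("degenerate designs are rejected", {
  expect_error(cohort_design(n_case = 0), "at least one subject")
  expect_error(cohort_design(regions = character(0)), "non-empty")
  expect_error(cohort_design(regions = c("HIP", "HIP")), "unique")
  expect_error(cohort_design(missing_rate = 1), "missing_rate")
})

test_that("null cohorts give exchangeable groups (uniform p-values)", {
  meta <- generate_metadata(cohort_design(), seed = 5)
  sim <- simulate_expression(meta, simulation_params(de_fraction = 0), seed = 5)
  E_log <- log_transform(sim$expression)
  # two-sample t-tests on per-subject means
  subj <- unique(meta$subject_id)
  dx <- meta$diagnosis[match(subj, meta$subject_id)]
  M <- vapply(subj, function(s) {
    rowMeans(E_log[, meta$subject_id == s, drop = FALSE])
  }, numeric(nrow(E_log)))
  pvals <- apply(M, 1, function(v) t.test(v[dx == "AD"], v[dx == "control"])$p.value)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("intraclass correlation matches tau^2 / (tau^2 + sigma^2)", {
  meta <- generate_metadata(cohort_design(missing_rate = 0), seed = 2)
  params <- simulation_params(
    n_genes = 2000, de_fraction = 0, subject_sd = 0.5,
    trend = function(mu) rep(0.5, length(mu)),
    region_effect_sd = 0, age_slope = 0, sex_shift = 0
  )
  sim <- simulate_expression(meta, params, seed = 2)
  E_log <- log2(sim$expression + 1)
  iccs <- apply(E_log, 1, icc_anova, groups = meta$subject_id)
  expect_equal(mean(iccs), 0.5, tolerance = 0.05 / 0.5)
  expect_lt(abs(mean(iccs) - 0.5), 0.05)
})

test_that("a planted log2 effect is recovered by subject means", {
  meta <- generate_metadata(cohort_design(missing_rate = 0), seed = 3)
  params <- simulation_params(
    n_genes = 400, de_fraction = 1, effect_size = 0.653, up_fraction = 1,
    subject_sd = 0.3, trend = function(mu) rep(0.3, length(mu)),
    region_effect_sd = 0, age_slope = 0, sex_shift = 0,
    baseline_dist = function(n) rep(6, n)
  )
  sim <- simulate_expression(meta, params, seed = 3)
  expect_true(all(sim$truth$true_logfc == 0.653))
  E_log <- log2(sim$expression + 1)
  subj <- unique(meta$subject_id)
  dx <- meta$diagnosis[match(subj, meta$subject_id)]
  M <- vapply(subj, function(s) {
    rowMeans(E_log[, meta$subject_id == s, drop = FALSE])
  }, numeric(nrow(E_log)))
  diffs <- rowMeans(M[, dx == "AD"]) - rowMeans(M[, dx == "control"])
  # Monte-Carlo error of the mean difference across 400 genes is ~0.01
  expect_equal(mean(diffs), 0.653, tolerance = 0.05)
})

test_that("residual sd tracks the injected mean-variance trend", {
  meta <- generate_metadata(cohort_design(), seed = 4)
  params <- simulation_params(n_genes = 2000, de_fraction = 0)
  sim <- simulate_expression(meta, params, seed = 4)
  E_adj <- adjust_covariates(log_transform(sim$expression), meta)
  fp <- first_pass_fit(E_adj, meta)
  ok <- !fp$flagged
  # bin genes by mean expression; binned sd must decrease with the trend
  bins <- cut(fp$avexp[ok], quantile(fp$avexp[ok], 0:20 / 20),
    include.lowest = TRUE
  )
  bin_sd <- tapply(fp$sqrt_sd[ok], bins, median)
  bin_mu <- tapply(fp$avexp[ok], bins, median)
  expect_gt(-cor(bin_mu, bin_sd, method = "spearman"), 0.9)
})

test_that("truth bookkeeping is exact", {
  meta <- tiny_meta()
  params <- simulation_params(n_genes = 100, de_fraction = 0.25)
  sim <- simulate_expression(meta, params, seed = 1)
  expect_equal(sum(sim$truth$is_de), round(0.25 * 100))
  expect_true(all(sim$truth$is_de == (sim$truth$true_logfc != 0)))
  # determinism
  sim2 <- simulate_expression(meta, params, seed = 1)
  expect_identical(sim$expression, sim2$expression)
  expect_equal(sim$truth, sim2$truth, ignore_attr = TRUE)
  # FPKM scale: non-negative
  expect_true(all(sim$expression >= 0))
})

test_that("non-positive trends are rejected", {
  meta <- tiny_meta()
  params <- simulation_params(
    n_genes = 10,
    trend = function(mu) mu * 0 - 1
  )
  expect_error(simulate_expression(meta, params, seed = 1), "positive")
})

test_that("fixtures round-trip losslessly through the readers", {
  meta <- tiny_meta()
  sim <- simulate_expression(meta, simulation_params(n_genes = 30, de_fraction = 0.1), seed = 9)
  dir <- withr::local_tempdir()
  paths <- write_fixture(sim$expression, meta, sim$truth, dir)
  E2 <- read_expression_matrix(paths[["expression"]])
  expect_equal(E2, sim$expression, tolerance = 1e-12)
  m2 <- read_metadata(paths[["metadata"]])
  expect_equal(m2$sample_id, meta$sample_id)
  expect_equal(m2$age, meta$age)
  t2 <- read_truth(paths[["truth"]])
  expect_equal(sum(t2$is_de), 3)
  # refuse overwrite without flag
  expect_error(write_fixture(sim$expression, meta, sim$truth, dir), "overwrite")
  # sample mismatch
  bad <- sim$expression
  colnames(bad)[1] <- "nope"
  expect_error(write_fixture(bad, meta, sim$truth, dir, overwrite = TRUE), "match")
})

test_that("cohort summary reports subject-level APOE carrier percentages", {
  meta <- generate_metadata(cohort_design(), seed = 1)
  cs <- cohort_summary(meta)
  expect_setequal(cs$diagnosis, c("AD", "control"))
  expect_equal(cs$n_subjects[cs$diagnosis == "AD"], 15)
  expect_equal(cs$n_subjects[cs$diagnosis == "control"], 30)
  expect_equal(sum(cs$n_samples), nrow(meta))
})
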