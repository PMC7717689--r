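#' Cohort design for the synthetic multi-region study
#'
#' Describes the sampling design of a two-group post-mortem brain cohort in
#' which each subject contributes at most one sample per brain region.
#' Defaults emulate a late-onset Alzheimer's study: 15 AD and 30 control
#' subjects, four regions (hippocampus HIP, temporal cortex TCx, parietal
#' cortex PCx, forebrain white matter FWM), and a per-(subject, region)
#' missingness rate tuned so that about 165 of the 180 possible samples are
#' retained.
#'
#' @param n_case number of case (AD) subjects, `>= 1`.
#' @param n_control number of control subjects, `>= 1`.
#' @param regions character vector of unique region labels.
#' @param missing_rate probability in `[0, 1)` that a given subject-region
#'   sample is absent. Missingness is uniform at random over subject-region
#'   pairs; a draw that removes all regions of a subject is redrawn so every
#'   subject keeps at least one sample.
#' @param age_mean,age_sd mean and sd (years) of age at death; draws are
#'   truncated at 60 (late-onset cohort).
#' @param sex_balance probability that a subject is female.
#' @param apoe4_rate_case,apoe4_rate_control per-group probability of
#'   carrying an APOE e4 allele.
#' @param seed default RNG seed used by [generate_metadata()].
#' @return an object of class `cohort_design` (a list of the above fields).
#' @examples
#' d <- cohort_design()
#' meta <- generate_metadata(d, seed = 1)
#' nrow(meta)
#' @export
cohort_design <- function(n_case = 15, n_control = 30,
                          regions = c("HIP", "TCx", "PCx", "FWM"),
                          missing_rate = 0.083,
                          age_mean = 88, age_sd = 6,
                          sex_balance = 0.44,
                          apoe4_rate_case = 1 / 3,
                          apoe4_rate_control = 0.10,
                          seed = 1L) {
  if (n_case < 1 || n_control < 1) stopf("need at least one subject per group")
  if (length(regions) == 0) stopf("regions must be non-empty")
  if (anyDuplicated(regions)) stopf("region labels must be unique")
  if (missing_rate < 0 || missing_rate >= 1) {
    stopf("missing_rate must be in [0, 1)")
  }
  if (age_sd < 0) stopf("age_sd must be non-negative")
  structure(
    list(
      n_case = as.integer(n_case), n_control = as.integer(n_control),
      regions = as.character(regions), missing_rate = missing_rate,
      age_mean = age_mean, age_sd = age_sd, sex_balance = sex_balance,
      apoe4_rate_case = apoe4_rate_case,
      apoe4_rate_control = apoe4_rate_control,
      seed = as.integer(seed)
    ),
    class = "cohort_design"
  )
}

#' Simulation parameters for synthetic expression
#'
#' Parameters of the generative model behind [simulate_expression()]. On the
#' log2 scale, the signal for gene g in sample i is
#' \deqn{y_{gi} = \mu_g + \delta_g \cdot AD_i + r_{g,region(i)} +
#'   \beta_{age}(age_i - \bar{age}) + \beta_{sex} female_i + u_{g,subj(i)} +
#'   \varepsilon_{gi}}
#' with subject random intercepts \eqn{u \sim N(0, \tau^2)} and residuals
#' \eqn{\varepsilon \sim N(0, \sigma(\mu_g)^2)} whose standard deviation
#' follows the mean-variance `trend`. The emitted matrix is FPKM-scale:
#' `pmax(2^y - offset, 0)`.
#'
#' @param n_genes number of genes.
#' @param de_fraction fraction pi in `[0, 1]` of genes that are truly
#'   differentially expressed; `round(pi * n_genes)` genes receive a
#'   non-zero log2 effect.
#' @param effect_size absolute log2 fold change delta given to DE genes.
#' @param up_fraction fraction of DE genes upregulated in cases (default 0.8,
#'   matching the predominance of upregulation seen in multi-region AD
#'   analyses).
#' @param subject_sd tau, the sd of the per-(gene, subject) random intercept,
#'   log2 units.
#' @param trend vectorized function mapping baseline log2 mean to residual
#'   sd; must be strictly positive over the baseline support. The default
#'   `0.2 + 1.5 * exp(-0.4 * mu)` decreases with expression, mimicking
#'   RNA-seq-like heteroskedasticity.
#' @param region_effect_sd sd of per-(gene, region) fixed shifts, log2 units.
#' @param age_slope log2 change per year of age.
#' @param sex_shift log2 shift for female subjects.
#' @param baseline_dist function of `n` returning baseline log2 means. The
#'   default `rnorm(n, 5, 1.5)` emulates expressed genes (average log2
#'   expression roughly 1-9); the floor at zero FPKM is then rarely active,
#'   so the log-scale generative structure survives the round trip to the
#'   FPKM scale.
#' @param log_offset offset used in the log2 <-> FPKM conversion (matches the
#'   default of [log_transform()]).
#' @return an object of class `simulation_params`.
#' @export
simulation_params <- function(n_genes = 2000,
                              de_fraction = 0.012,
                              effect_size = 0.6,
                              up_fraction = 0.8,
                              subject_sd = 0.5,
                              trend = function(mu) 0.2 + 1.5 * exp(-0.4 * mu),
                              region_effect_sd = 0.5,
                              age_slope = 0.01,
                              sex_shift = 0.1,
                              baseline_dist = function(n) rnorm(n, 5, 1.5),
                              log_offset = 1) {
  if (n_genes < 1) stopf("n_genes must be >= 1")
  if (de_fraction < 0 || de_fraction > 1) stopf("de_fraction must be in [0, 1]")
  if (subject_sd < 0) stopf("subject_sd must be >= 0")
  if (!is.function(trend)) stopf("trend must be a function")
  if (!is.function(baseline_dist)) stopf("baseline_dist must be a function")
  if (log_offset <= 0) stopf("log_offset must be positive")
  structure(
    list(
      n_genes = as.integer(n_genes), de_fraction = de_fraction,
      effect_size = effect_size, up_fraction = up_fraction,
      subject_sd = subject_sd, trend = trend,
      region_effect_sd = region_effect_sd, age_slope = age_slope,
      sex_shift = sex_shift, baseline_dist = baseline_dist,
      log_offset = log_offset
    ),
    class = "simulation_params"
  )
}

#' Generate sample metadata for a synthetic cohort
#'
#' Draws subject-level covariates (age truncated at 60, sex, APOE e4
#' carriership, Braak stage) and a subject-region sample table with uniform
#' missingness. Diagnosis is constant within subject and every subject
#' retains at least one region (all-missing draws are redrawn).
#'
#' @param design a [cohort_design()].
#' @param seed RNG seed; defaults to `design$seed`. The output is
#'   deterministic given `(design, seed)`.
#' @return a data.frame with columns
#'   `sample_id, subject_id, region, diagnosis, age, sex, apoe4, braak`,
#'   one row per retained subject-region sample.
#' @export
generate_metadata <- function(design, seed = design$seed) {
  if (!inherits(design, "cohort_design")) {
    stopf("design must be created by cohort_design()")
  }
  set.seed(seed)
  n_sub <- design$n_case + design$n_control
  subject_id <- c(
    sprintf("AD%02d", seq_len(design$n_case)),
    sprintf("C%02d", seq_len(design$n_control))
  )
  diagnosis <- rep(c("AD", "control"), c(design$n_case, design$n_control))

  age <- rnorm(n_sub, design$age_mean, design$age_sd)
  while (any(age < 60)) { # truncate: late-onset cohort, death at >= 60
    idx <- age < 60
    age[idx] <- rnorm(sum(idx), design$age_mean, design$age_sd)
  }
  age <- round(age, 1)
  sex <- ifelse(runif(n_sub) < design$sex_balance, "F", "M")
  apoe4 <- as.integer(runif(n_sub) < ifelse(diagnosis == "AD",
    design$apoe4_rate_case, design$apoe4_rate_control
  ))
  braak_mean <- ifelse(diagnosis == "AD", 4.1, 2.7)
  braak <- pmin(6L, pmax(0L, as.integer(round(rnorm(n_sub, braak_mean, 1.5)))))

  n_reg <- length(design$regions)
  keep <- matrix(runif(n_sub * n_reg) >= design$missing_rate, n_sub, n_reg)
  for (s in seq_len(n_sub)) { # every subject keeps >= 1 region
    while (!any(keep[s, ])) {
      keep[s, ] <- runif(n_reg) >= design$missing_rate
    }
  }

  rows <- which(keep, arr.ind = TRUE)
  rows <- rows[order(rows[, 1], rows[, 2]), , drop = FALSE]
  s <- rows[, 1]
  r <- rows[, 2]
  out <- data.frame(
    sample_id = paste0(subject_id[s], "_", design$regions[r]),
    subject_id = subject_id[s],
    region = design$regions[r],
    diagnosis = diagnosis[s],
    age = age[s],
    sex = sex[s],
    apoe4 = apoe4[s],
    braak = braak[s],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Simulate an FPKM-scale expression matrix with known ground truth
#'
#' Generates gene expression according to the hierarchical model described
#' in [simulation_params()]: per-gene baselines, planted case/control log2
#' effects for a `de_fraction` of genes, per-(gene, region) shifts, age and
#' sex covariate effects, per-(gene, subject) random intercepts, and
#' heteroskedastic residual noise whose sd follows the mean-variance trend.
#'
#' @param meta metadata as from [generate_metadata()].
#' @param params a [simulation_params()].
#' @param seed RNG seed.
#' @return a list with elements `expression` (genes x samples FPKM-scale
#'   matrix) and `truth` (data.frame `gene_id, is_de, true_logfc`, plus the
#'   parameters as attribute `"params"`).
#' @export
simulate_expression <- function(meta, params = simulation_params(), seed = 1L) {
  if (!is.data.frame(meta) || nrow(meta) == 0) stopf("meta must be non-empty")
  if (!inherits(params, "simulation_params")) {
    stopf("params must be created by simulation_params()")
  }
  set.seed(seed)
  G <- params$n_genes
  n <- nrow(meta)
  gene_id <- sprintf("G%05d", seq_len(G))

  baseline <- params$baseline_dist(G)
  res_sd <- params$trend(baseline)
  if (any(!is.finite(res_sd)) || any(res_sd <= 0)) {
    stopf("trend must be strictly positive over the baseline support")
  }

  n_de <- round(params$de_fraction * G)
  de_idx <- if (n_de > 0) sample.int(G, n_de) else integer(0)
  true_logfc <- numeric(G)
  if (n_de > 0) {
    up <- runif(n_de) < params$up_fraction
    true_logfc[de_idx] <- ifelse(up, 1, -1) * params$effect_size
  }

  subjects <- unique(meta$subject_id)
  sub_idx <- match(meta$subject_id, subjects)
  regions <- unique(meta$region)
  reg_idx <- match(meta$region, regions)
  is_ad <- as.numeric(meta$diagnosis == "AD")
  age_c <- meta$age - mean(meta$age)
  female <- encode_sex(meta$sex)

  # per-gene x subject random intercepts, per-gene x region shifts
  U <- matrix(rnorm(G * length(subjects), 0, params$subject_sd),
    G, length(subjects)
  )
  R <- matrix(rnorm(G * length(regions), 0, params$region_effect_sd),
    G, length(regions)
  )

  signal <- matrix(baseline, G, n) +
    outer(true_logfc, is_ad) +
    R[, reg_idx, drop = FALSE] +
    matrix(params$age_slope * age_c, G, n, byrow = TRUE) +
    matrix(params$sex_shift * female, G, n, byrow = TRUE) +
    U[, sub_idx, drop = FALSE] +
    matrix(rnorm(G * n, 0, rep(res_sd, n)), G, n)

  E <- pmax(2^signal - params$log_offset, 0)
  dimnames(E) <- list(gene_id, meta$sample_id)

  truth <- data.frame(
    gene_id = gene_id,
    is_de = true_logfc != 0,
    true_logfc = true_logfc,
    stringsAsFactors = FALSE
  )
  attr(truth, "params") <- params
  list(expression = E, truth = truth)
}

#' Write a synthetic fixture to disk
#'
#' Writes the expression matrix (TSV), sample metadata (CSV) and ground
#' truth (CSV) in the formats accepted by [read_expression_matrix()],
#' [read_metadata()] and [read_truth()], so that the fixture round-trips
#' losslessly.
#'
#' @param expression genes x samples matrix.
#' @param meta sample metadata.
#' @param truth ground-truth table.
#' @param dir output directory (created if absent).
#' @param overwrite allow overwriting existing files.
#' @return invisibly, a named character vector of the three file paths.
#' @export
write_fixture <- function(expression, meta, truth, dir, overwrite = FALSE) {
  check_expression_matrix(expression, non_negative = TRUE)
  check_meta_matches(expression, meta)
  if (!setequal(rownames(expression), truth$gene_id)) {
    stopf("gene IDs of expression matrix and truth table do not match")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    metadata = file.path(dir, "metadata.csv"),
    truth = file.path(dir, "truth.csv")
  )
  if (!overwrite && any(file.exists(paths))) {
    stopf("fixture files already exist in '%s' (use overwrite = TRUE)", dir)
  }
  write_expression_matrix(expression, paths[["expression"]])
  write_metadata(meta, paths[["metadata"]])
  write.csv(truth, paths[["truth"]], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Summarize a cohort's demographics by diagnosis
#'
#' Subject-level summary: counts, mean (sd) age, sex split, APOE e4 carrier
#' counts and percentages, mean Braak stage, and sample counts per group.
#'
#' @param meta sample metadata with one row per sample.
#' @return data.frame with one row per diagnosis group.
#' @examples
#' meta <- generate_metadata(cohort_design(), seed = 1)
#' cohort_summary(meta)
#' @export
cohort_summary <- function(meta) {
  req <- c("sample_id", "subject_id", "diagnosis")
  if (!all(req %in% names(meta))) {
    stopf("metadata must contain columns %s", paste(req, collapse = ", "))
  }
  subj <- meta[!duplicated(meta$subject_id), , drop = FALSE]
  groups <- sort(unique(subj$diagnosis))
  out <- do.call(rbind, lapply(groups, function(g) {
    sg <- subj[subj$diagnosis == g, , drop = FALSE]
    data.frame(
      diagnosis = g,
      n_subjects = nrow(sg),
      n_samples = sum(meta$diagnosis == g),
      age_mean = if ("age" %in% names(sg)) mean(sg$age) else NA_real_,
      age_sd = if ("age" %in% names(sg)) sd(sg$age) else NA_real_,
      n_female = if ("sex" %in% names(sg)) sum(encode_sex(sg$sex)) else NA_integer_,
      apoe4_carriers = if ("apoe4" %in% names(sg)) sum(sg$apoe4 == 1) else NA_integer_,
      apoe4_pct = if ("apoe4" %in% names(sg)) {
        round(100 * mean(sg$apoe4 == 1), 2)
      } else {
        NA_real_
      },
      braak_mean = if ("braak" %in% names(sg)) mean(sg$braak) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
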