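#' Assemble a pipeline run configuration
#'
#' Collects paths, thresholds and per-stage parameter blocks for the
#' orchestration helpers [run_simulate()], [run_de()], [run_enrich()] and
#' [run_classify()]. Defaults follow the analysis protocol: Bonferroni DE
#' gate at alpha 0.05, GSEA gates p < .01 and FDR < .02, ORA Bonferroni
#' gate 0.05.
#'
#' @param out_dir output directory (created if needed).
#' @param expression,metadata,gmt input paths (or NULL where unused).
#' @param regions optional character vector restricting the analysis to a
#'   subset of regions.
#' @param seed master seed for every stochastic stage.
#' @param alpha Bonferroni significance threshold for the DE gate.
#' @param preprocess list: `log_offset`, `covariates`, `order`
#'   (`"log_then_adjust"` or `"adjust_then_log"`).
#' @param voom list: `span`, `iterations`.
#' @param model list: `region_effect`, `df_method`.
#' @param enrichment list: `n_perm`, `exponent`, `min_size`, `max_size`,
#'   `p_thresh`, `fdr_thresh`, `ora_alpha`.
#' @param classify list: `train_frac`, `delta`, `n_top`, `classifiers`,
#'   `sizes`, `rf_ntree`.
#' @param simulate list: `design` (a [cohort_design()]) and `params`
#'   (a [simulation_params()]).
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       expression = NULL, metadata = NULL, gmt = NULL,
                       regions = NULL, seed = 1L, alpha = 0.05,
                       preprocess = list(), voom = list(), model = list(),
                       enrichment = list(), classify = list(),
                       simulate = list()) {
  if (alpha <= 0 || alpha > 1) stopf("alpha must be in (0, 1]")
  defaults <- list(
    preprocess = list(
      log_offset = 1, covariates = c("age", "sex"),
      order = "log_then_adjust"
    ),
    voom = list(span = 0.5, iterations = 3),
    model = list(region_effect = FALSE, df_method = "between_within"),
    enrichment = list(
      n_perm = 1000, exponent = 1, min_size = 5, max_size = 500,
      p_thresh = 0.01, fdr_thresh = 0.02, ora_alpha = 0.05
    ),
    classify = list(
      train_frac = 0.7, delta = 0.5, n_top = 10,
      classifiers = c(
        "svm_linear", "svm_rbf", "random_forest",
        "quadratic_bayes"
      ),
      sizes = 2:10, rf_ntree = 500
    ),
    simulate = list(design = cohort_design(), params = simulation_params())
  )
  merge_block <- function(name, given) {
    out <- defaults[[name]]
    for (k in names(given)) out[[k]] <- given[[k]]
    out
  }
  structure(
    list(
      out_dir = out_dir, expression = expression, metadata = metadata,
      gmt = gmt, regions = regions, seed = as.integer(seed), alpha = alpha,
      preprocess = merge_block("preprocess", preprocess),
      voom = merge_block("voom", voom),
      model = merge_block("model", model),
      enrichment = merge_block("enrichment", enrichment),
      classify = merge_block("classify", classify),
      simulate = merge_block("simulate", simulate)
    ),
    class = "run_config"
  )
}

provenance_lines <- function(config) {
  c(
    sprintf("hierde %s", as.character(packageVersion("hierde"))),
    sprintf("seed=%d", config$seed),
    sprintf("config=%s", config_hash(config[setdiff(names(config), "simulate")]))
  )
}

ensure_dir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

load_inputs <- function(config) {
  if (is.null(config$expression) || is.null(config$metadata)) {
    stopf("config must provide expression and metadata paths")
  }
  E <- read_expression_matrix(config$expression)
  meta <- read_metadata(config$metadata)
  if (!is.null(config$regions)) {
    keep <- meta$region %in% config$regions
    if (!any(keep)) stopf("no samples in the requested regions")
    meta <- meta[keep, , drop = FALSE]
    E <- E[, meta$sample_id, drop = FALSE]
  }
  check_meta_matches(E, meta)
  list(E = E, meta = align_meta(E, meta))
}

# shared preprocessing + weighting + mixed-model front end
de_pipeline <- function(E, meta, config) {
  pp <- config$preprocess
  if (identical(pp$order, "adjust_then_log")) {
    # literal adjust-then-log: OLS residuals of raw values can be negative,
    # so the gene grand mean is restored and values floored just above 0
    warnf("adjust_then_log floors negative adjusted FPKM at a small positive value")
    E_adj_raw <- adjust_covariates(E, meta, pp$covariates)
    E_adj_raw <- pmax(E_adj_raw, 1e-6)
    E_log <- log_transform(E_adj_raw, pp$log_offset)
    E_adj <- E_log
  } else {
    E_log <- log_transform(E, pp$log_offset)
    E_adj <- adjust_covariates(E_log, meta, pp$covariates)
  }
  spec <- model_spec(region_effect = config$model$region_effect)
  vw <- voom_weights(E_adj, meta, spec,
    span = config$voom$span,
    iterations = config$voom$iterations
  )
  fits <- fit_all(E_adj, vw$weights, meta, spec,
    df_method = config$model$df_method
  )
  list(E_log = E_adj, weights = vw, fits = fits, spec = spec)
}

#' Simulate a cohort fixture to disk
#'
#' Wraps [generate_metadata()], [simulate_expression()] and
#' [write_fixture()], and writes a `manifest.json` recording the seed and
#' generator parameters so the fixture can be re-created byte-identically.
#'
#' @param config a [run_config()] whose `simulate` block holds the design
#'   and parameters.
#' @return invisibly, the named vector of written paths.
#' @export
run_simulate <- function(config) {
  ensure_dir(config$out_dir)
  design <- config$simulate$design
  params <- config$simulate$params
  meta <- generate_metadata(design, seed = config$seed)
  sim <- simulate_expression(meta, params, seed = config$seed)
  paths <- write_fixture(sim$expression, meta, sim$truth, config$out_dir,
    overwrite = TRUE
  )
  manifest <- list(
    seed = config$seed,
    design = design[setdiff(names(design), character(0))],
    params = params[
      setdiff(names(params), c("trend", "baseline_dist"))
    ],
    n_samples = nrow(meta),
    n_genes = nrow(sim$expression)
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, manifest = manifest_path))
}

#' Run the differential-expression stage
#'
#' Executes preprocessing, voom-style weighting and the per-gene mixed
#' model, then empirical-Bayes moderation, Bonferroni correction and the
#' B-statistic. Writes `de_results.csv` (with provenance comment header)
#' and returns the table plus a summary. Optionally runs the per-region
#' Wilcoxon comparison.
#'
#' @param config a [run_config()].
#' @param wilcoxon also compute per-region Wilcoxon rank-sum p-values.
#' @return list: `de` (results table), `summary` (list: `m`,
#'   `n_significant`, `n_up`, `n_down`, `alpha`), `wilcoxon` (per-region
#'   matrix of p-values or NULL), `paths`.
#' @export
run_de <- function(config, wilcoxon = FALSE) {
  ensure_dir(config$out_dir)
  inputs <- load_inputs(config)
  stage <- tryCatch(
    de_pipeline(inputs$E, inputs$meta, config),
    error = function(e) stopf("[de] model stage failed: %s", conditionMessage(e))
  )
  de <- de_results(stage$fits)
  sig <- !is.na(de$adj.P.Val) & de$adj.P.Val < config$alpha
  summary <- list(
    m = nrow(de),
    n_significant = sum(sig),
    n_up = sum(sig & de$logFC > 0),
    n_down = sum(sig & de$logFC < 0),
    alpha = config$alpha
  )
  wilc <- NULL
  if (wilcoxon) {
    regions <- unique(inputs$meta$region)
    wilc <- vapply(
      regions,
      function(r) wilcoxon_region(stage$E_log, inputs$meta, r),
      numeric(nrow(stage$E_log))
    )
    colnames(wilc) <- regions
  }
  de_path <- file.path(config$out_dir, "de_results.csv")
  write_de_table(de, de_path, comments = provenance_lines(config))
  trend_path <- file.path(config$out_dir, "mean_variance_trend.png")
  try(plot_trend(stage$weights$first_pass, stage$weights$trend, trend_path),
    silent = TRUE
  )
  list(
    de = de, summary = summary, wilcoxon = wilc,
    paths = c(de = de_path)
  )
}

#' Run the enrichment stage
#'
#' Over-representation analysis of the Bonferroni-significant genes against
#' the GMT collection (universe = all genes in the DE table) and pre-ranked
#' GSEA of all genes ordered by moderated t. When no gene passes the DE
#' gate, ORA is skipped with a notice and GSEA still runs.
#'
#' @param config a [run_config()]; `gmt` must be set.
#' @param de DE results table (from [run_de()]); read from
#'   `out_dir/de_results.csv` when NULL.
#' @return list: `ora` (data.frame or NULL), `gsea`, `gsea_up`,
#'   `gsea_down` (tables at the p/FDR gates), `edges`, `paths`.
#' @export
run_enrich <- function(config, de = NULL) {
  ensure_dir(config$out_dir)
  if (is.null(config$gmt)) stopf("config$gmt must point to a GMT file")
  sets <- read_gmt(config$gmt)
  if (is.null(de)) de <- read_de_table(file.path(config$out_dir, "de_results.csv"))
  en <- config$enrichment

  sig <- de$gene_id[!is.na(de$adj.P.Val) & de$adj.P.Val < config$alpha]
  ora <- NULL
  if (length(sig) == 0) {
    message("[enrich] no Bonferroni-significant genes; ORA skipped")
  } else {
    ora <- ora_test(sig, sets, universe = de$gene_id)
  }

  ranked <- de[!is.na(de$t), , drop = FALSE]
  metric <- setNames(ranked$t, ranked$gene_id)
  gsea <- gsea_preranked(metric, sets,
    n_perm = en$n_perm, exponent = en$exponent,
    min_size = en$min_size, max_size = en$max_size, seed = config$seed
  )
  pass <- gsea$p_perm < en$p_thresh & gsea$fdr < en$fdr_thresh
  gsea_up <- gsea[pass & gsea$nes > 0, , drop = FALSE]
  gsea_down <- gsea[pass & gsea$nes < 0, , drop = FALSE]
  edges <- similarity_edges(sets)

  paths <- c(
    gsea = file.path(config$out_dir, "gsea_results.csv"),
    edges = file.path(config$out_dir, "enrichment_map_edges.tsv")
  )
  write_de_table(gsea, paths[["gsea"]], comments = provenance_lines(config))
  write.table(edges, paths[["edges"]],
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  if (!is.null(ora)) {
    paths <- c(paths, ora = file.path(config$out_dir, "ora_results.csv"))
    write_de_table(ora, paths[["ora"]], comments = provenance_lines(config))
  }
  list(
    ora = ora, gsea = gsea, gsea_up = gsea_up, gsea_down = gsea_down,
    edges = edges, paths = paths
  )
}

#' Run the gene-panel classification stage
#'
#' Selects the top `n_top` genes by corrected p-value (overridable), builds
#' a subject-disjoint 70/30 split, and performs the exhaustive panel search
#' for each configured classifier, reporting test metrics and Hoeffding
#' bounds.
#'
#' @param config a [run_config()].
#' @param de DE results table; read from `out_dir/de_results.csv` when NULL.
#' @param genes optional explicit candidate gene list (overrides top-10
#'   selection).
#' @return list: `report` (one row per classifier x panel size), `split`,
#'   `genes`, `paths`.
#' @export
run_classify <- function(config, de = NULL, genes = NULL) {
  ensure_dir(config$out_dir)
  inputs <- load_inputs(config)
  if (is.null(de) && is.null(genes)) {
    de <- read_de_table(file.path(config$out_dir, "de_results.csv"))
  }
  cl <- config$classify
  if (is.null(genes)) {
    ranked <- de[order(de$adj.P.Val, de$P.Value), ]
    ranked <- ranked[ranked$gene_id %in% rownames(inputs$E), ]
    if (nrow(ranked) < cl$n_top) {
      stopf(
        "fewer than %d usable genes; pass an explicit gene list",
        cl$n_top
      )
    }
    genes <- ranked$gene_id[seq_len(cl$n_top)]
  }
  missing <- setdiff(genes, rownames(inputs$E))
  if (length(missing)) {
    stopf("candidate gene(s) absent from expression: %s", paste(missing, collapse = ", "))
  }
  E_log <- log_transform(inputs$E, config$preprocess$log_offset)
  X <- t(E_log[genes, , drop = FALSE])
  split <- split_by_subject(inputs$meta,
    train_frac = cl$train_frac,
    seed = config$seed
  )
  labels <- inputs$meta$diagnosis[match(rownames(X), inputs$meta$sample_id)]
  report <- do.call(rbind, lapply(cl$classifiers, function(cf) {
    opts <- if (cf == "random_forest") list(ntree = cl$rf_ntree) else list()
    panel_search(X, labels, cf, split,
      sizes = cl$sizes, delta = cl$delta,
      opts = opts, seed = config$seed
    )
  }))
  path <- file.path(config$out_dir, "panel_report.csv")
  write_de_table(report, path, comments = provenance_lines(config))
  list(report = report, split = split, genes = genes, paths = c(report = path))
}

#' Run every stage end to end
#'
#' @param config a [run_config()]; when `expression` is NULL a synthetic
#'   fixture is first generated into `out_dir`.
#' @param wilcoxon forwarded to [run_de()].
#' @return list with the per-stage results.
#' @export
run_all <- function(config, wilcoxon = FALSE) {
  if (is.null(config$expression)) {
    paths <- run_simulate(config)
    config$expression <- paths[["expression"]]
    config$metadata <- paths[["metadata"]]
  }
  de <- run_de(config, wilcoxon = wilcoxon)
  enrich <- if (!is.null(config$gmt)) run_enrich(config, de = de$de) else NULL
  classify <- run_classify(config, de = de$de)
  list(de = de, enrich = enrich, classify = classify)
}
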