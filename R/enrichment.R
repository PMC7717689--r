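#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the selected gene list overlaps the set
#' more than expected by chance within the given universe:
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)` with universe size
#' `N`, in-universe set size `K`, selection size `n`, and overlap `k`.
#' Bonferroni correction is over the number of sets tested.
#'
#' @param selected character vector of selected gene IDs (e.g. the
#'   Bonferroni-significant genes). Genes outside the universe are dropped
#'   with a warning.
#' @param sets a `gene_set_collection` (see [read_gmt()]) or named list of
#'   character vectors.
#' @param universe character vector of all testable gene IDs (deduplicated).
#' @return data.frame: `set, universe_size, set_size, selected, overlap,
#'   p_raw, p_bonf`, in the input set order.
#' @export
ora_test <- function(selected, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stopf("universe is empty")
  selected <- unique(selected)
  if (length(selected) == 0) stopf("selection is empty")
  outside <- setdiff(selected, universe)
  if (length(outside)) {
    warnf("%d selected gene(s) outside the universe dropped", length(outside))
    selected <- intersect(selected, universe)
    if (length(selected) == 0) stopf("no selected genes in the universe")
  }
  members <- gene_set_members(sets)
  N <- length(universe)
  n <- length(selected)
  T_sets <- length(members)
  rows <- lapply(seq_along(members), function(i) {
    in_univ <- intersect(members[[i]], universe)
    K <- length(in_univ)
    k <- length(intersect(in_univ, selected))
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(
      set = names(members)[i], universe_size = N, set_size = K,
      selected = n, overlap = k, p_raw = p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_bonf <- pmin(1, T_sets * out$p_raw)
  rownames(out) <- NULL
  out
}

# running-sum enrichment statistic from a hit indicator over a ranked list
es_from_hits <- function(wts, hit) {
  n_hit <- sum(hit)
  denom_hit <- sum(wts[hit])
  if (denom_hit <= 0) { # all in-set scores zero: fall back to unweighted hits
    phit <- cumsum(hit) / n_hit
  } else {
    phit <- cumsum(ifelse(hit, wts, 0)) / denom_hit
  }
  pmiss <- cumsum(!hit) / (length(hit) - n_hit)
  rs <- phit - pmiss
  rs[which.max(abs(rs))]
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked gene list from top to bottom, incrementing a running
#' statistic by the (normalized) `|score|^exponent` at set members and
#' decrementing by `1/(N - N_set)` elsewhere; the enrichment score ES is
#' the running value of maximal absolute magnitude. `exponent = 0` gives
#' the classic Kolmogorov-Smirnov statistic, `exponent = 1` the standard
#' weighted form.
#'
#' @param scores named numeric vector, ordered from best to worst rank
#'   (the ordering is taken as given).
#' @param set character vector of member gene IDs; must hit at least one
#'   but not all ranked genes.
#' @param exponent weighting exponent `p >= 0`.
#' @return list `es` (scalar) and `running` (the running statistic, one
#'   value per ranked gene).
#' @export
enrichment_score <- function(scores, set, exponent = 1) {
  if (is.null(names(scores))) stopf("scores must be named by gene ID")
  if (any(!is.finite(scores))) stopf("scores must be finite")
  hit <- names(scores) %in% set
  if (!any(hit)) stopf("gene set has no member in the ranked list")
  if (all(hit)) stopf("gene set covers the whole ranked list")
  wts <- abs(scores)^exponent
  n_hit <- sum(hit)
  denom_hit <- sum(wts[hit])
  if (denom_hit <= 0) {
    phit <- cumsum(hit) / n_hit
  } else {
    phit <- cumsum(ifelse(hit, wts, 0)) / denom_hit
  }
  pmiss <- cumsum(!hit) / (length(hit) - n_hit)
  rs <- phit - pmiss
  list(es = rs[which.max(abs(rs))], running = unname(rs))
}

#' Pre-ranked gene-set enrichment analysis
#'
#' Ranks genes by the supplied metric (decreasing; ties broken by gene ID
#' for determinism), computes each set's weighted running-sum enrichment
#' score, and assesses significance by gene-set permutation: `n_perm`
#' random sets of matching size drawn from the ranked list. The normalized
#' enrichment score NES is ES divided by the mean magnitude of same-sign
#' null ES; the permutation p-value is the add-one-smoothed fraction of
#' same-sign null ES at least as extreme; the FDR q-value compares the
#' pooled normalized null NES distribution with the observed NES, per the
#' usual GSEA convention.
#'
#' @param metric named numeric vector (gene -> score, e.g. moderated t).
#' @param sets a `gene_set_collection` or named list of character vectors.
#' @param n_perm number of permutations (>= 100).
#' @param exponent weighting exponent (default 1).
#' @param min_size,max_size mapped-size bounds; sets outside are skipped.
#' @param seed RNG seed (results are deterministic given the seed).
#' @return data.frame: `set, size, es, nes, p_perm, fdr`, in input set
#'   order for the sets retained.
#' @export
gsea_preranked <- function(metric, sets, n_perm = 1000, exponent = 1,
                           min_size = 5, max_size = 500, seed = 1L) {
  if (n_perm < 100) stopf("n_perm must be >= 100")
  if (is.null(names(metric))) stopf("metric must be named by gene ID")
  o <- order(-metric, names(metric))
  metric <- metric[o]
  genes <- names(metric)
  N <- length(genes)
  tie_frac <- 1 - length(unique(metric)) / N
  if (tie_frac > 0.5) warnf("more than half of the ranking metric is tied; ranks are unstable")
  wts <- abs(metric)^exponent

  members <- gene_set_members(sets)
  mapped <- lapply(members, function(m) which(genes %in% m))
  sizes <- lengths(mapped)
  keep <- sizes >= min_size & sizes <= max_size & sizes < N
  if (!any(keep)) stopf("no gene set within the size bounds after mapping")
  mapped <- mapped[keep]
  sizes <- sizes[keep]

  set.seed(seed)
  es_obs <- numeric(length(mapped))
  nes <- p_perm <- numeric(length(mapped))
  null_nes_all <- vector("list", length(mapped))
  for (i in seq_along(mapped)) {
    hit <- rep(FALSE, N)
    hit[mapped[[i]]] <- TRUE
    es_obs[i] <- es_from_hits(wts, hit)
    null_es <- vapply(seq_len(n_perm), function(b) {
      h <- rep(FALSE, N)
      h[sample.int(N, sizes[i])] <- TRUE
      es_from_hits(wts, h)
    }, numeric(1))
    pos <- null_es[null_es >= 0]
    neg <- null_es[null_es < 0]
    mean_pos <- if (length(pos)) mean(pos) else NA_real_
    mean_neg <- if (length(neg)) mean(abs(neg)) else NA_real_
    if (es_obs[i] >= 0) {
      nes[i] <- if (is.finite(mean_pos) && mean_pos > 0) es_obs[i] / mean_pos else NA_real_
      p_perm[i] <- (1 + sum(pos >= es_obs[i])) / (1 + length(pos))
    } else {
      nes[i] <- if (is.finite(mean_neg) && mean_neg > 0) es_obs[i] / mean_neg else NA_real_
      p_perm[i] <- (1 + sum(abs(neg) >= abs(es_obs[i]))) / (1 + length(neg))
    }
    null_nes_all[[i]] <- c(
      if (is.finite(mean_pos) && mean_pos > 0) pos / mean_pos else numeric(0),
      if (is.finite(mean_neg) && mean_neg > 0) -abs(neg) / mean_neg else numeric(0)
    )
  }

  null_nes <- unlist(null_nes_all)
  fdr <- vapply(seq_along(nes), function(i) {
    s <- nes[i]
    if (!is.finite(s)) {
      return(NA_real_)
    }
    if (s >= 0) {
      num_pool <- sum(null_nes >= 0)
      num <- if (num_pool) sum(null_nes >= s) / num_pool else 1
      den_pool <- sum(nes >= 0, na.rm = TRUE)
      den <- if (den_pool) sum(nes >= s, na.rm = TRUE) / den_pool else 1
    } else {
      num_pool <- sum(null_nes < 0)
      num <- if (num_pool) sum(null_nes <= s) / num_pool else 1
      den_pool <- sum(nes < 0, na.rm = TRUE)
      den <- if (den_pool) sum(nes <= s, na.rm = TRUE) / den_pool else 1
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))

  data.frame(
    set = names(mapped), size = sizes, es = es_obs, nes = nes,
    p_perm = p_perm, fdr = fdr,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Similarity coefficients between two gene sets
#'
#' Edge weights for enrichment-map graphs: the Jaccard index
#' `|A n B| / |A u B|`, the overlap coefficient `|A n B| / min(|A|, |B|)`,
#' and their equal-weight combination.
#'
#' @param a,b character vectors of gene IDs (non-empty; deduplicated).
#' @return named list `jaccard`, `overlap`, `combined`.
#' @export
set_similarity <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0 || length(b) == 0) stopf("sets must be non-empty")
  inter <- length(intersect(a, b))
  jac <- inter / length(union(a, b))
  ov <- inter / min(length(a), length(b))
  list(jaccard = jac, overlap = ov, combined = 0.5 * jac + 0.5 * ov)
}

#' Pairwise similarity edge list for an enrichment map
#'
#' @param sets a `gene_set_collection` or named list of character vectors.
#' @param min_combined minimum combined similarity for an edge to be kept.
#' @return data.frame `set_a, set_b, jaccard, overlap, combined`.
#' @export
similarity_edges <- function(sets, min_combined = 0.375) {
  members <- gene_set_members(sets)
  nm <- names(members)
  if (length(members) < 2) {
    return(data.frame(
      set_a = character(0), set_b = character(0), jaccard = numeric(0),
      overlap = numeric(0), combined = numeric(0)
    ))
  }
  pairs <- combn(length(members), 2)
  rows <- apply(pairs, 2, function(ij) {
    s <- set_similarity(members[[ij[1]]], members[[ij[2]]])
    data.frame(
      set_a = nm[ij[1]], set_b = nm[ij[2]], jaccard = s$jaccard,
      overlap = s$overlap, combined = s$combined, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[out$combined >= min_combined, , drop = FALSE]
}
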