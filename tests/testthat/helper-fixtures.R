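# Shared fixtures and independent oracles used across the suite.

# small multi-region cohort metadata built by hand (no RNG)
tiny_meta <- function(n_case = 3, n_control = 3,
                      regions = c("HIP", "TCx")) {
  subjects <- c(sprintf("AD%02d", seq_len(n_case)),
                sprintf("C%02d", seq_len(n_control)))
  dx <- rep(c("AD", "control"), c(n_case, n_control))
  grid <- expand.grid(s = seq_along(subjects), r = seq_along(regions))
  grid <- grid[order(grid$s, grid$r), ]
  data.frame(
    sample_id = paste0(subjects[grid$s], "_", regions[grid$r]),
    subject_id = subjects[grid$s],
    region = regions[grid$r],
    diagnosis = dx[grid$s],
    age = 80 + grid$s,
    sex = rep(c("F", "M"), length.out = nrow(grid)),
    apoe4 = 0L,
    braak = 3L,
    stringsAsFactors = FALSE
  )
}

# expression matrix with given dimnames filled from a deterministic stream
tiny_matrix <- function(genes, samples, seed = 1) {
  set.seed(seed)
  matrix(abs(rnorm(length(genes) * length(samples), 5, 2)),
    length(genes), length(samples),
    dimnames = list(genes, samples)
  )
}

# --- independent oracles ----------------------------------------------------

# hypergeometric upper-tail by direct enumeration of binomial coefficients
hyper_tail_oracle <- function(N, K, n, k) {
  js <- k:min(K, n)
  js <- js[(n - js) <= (N - K)]
  if (length(js) == 0) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# brute-force running-sum enrichment score, elementwise loop
es_oracle <- function(scores, set, exponent) {
  genes <- names(scores)
  scores <- unname(scores)
  N <- length(genes)
  in_set <- genes %in% set
  Ns <- sum(in_set)
  denom <- sum(abs(scores[in_set])^exponent)
  phit <- 0
  pmiss <- 0
  best <- 0
  for (i in seq_len(N)) {
    if (in_set[i]) {
      phit <- phit + abs(scores[i])^exponent / denom
    } else {
      pmiss <- pmiss + 1 / (N - Ns)
    }
    if (abs(phit - pmiss) > abs(best)) best <- phit - pmiss
  }
  best
}

# ordinary least squares through explicit normal equations
ols_oracle <- function(y, X) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  list(beta = drop(beta), sigma2 = sum(res^2) / (length(y) - ncol(X)))
}

# one-way ANOVA intraclass correlation estimator
icc_anova <- function(values, groups) {
  groups <- factor(groups)
  k <- tabulate(groups)
  n <- length(values)
  q <- nlevels(groups)
  grand <- mean(values)
  gm <- tapply(values, groups, mean)
  ssb <- sum(k * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  msb <- ssb / (q - 1)
  msw <- ssw / (n - q)
  k0 <- (n - sum(k^2) / n) / (q - 1)
  (msb - msw) / (msb + (k0 - 1) * msw)
}

write_tmp_gmt <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
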