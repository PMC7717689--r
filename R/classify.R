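#' Subject-disjoint train/test split
#'
#' Assigns whole subjects (never individual samples) to train or test,
#' stratified by diagnosis, so that no subject contributes samples to both
#' sides. Within each diagnosis group the subjects are randomly ordered and
#' the per-group train counts are chosen jointly so the total number of
#' training samples is as close as possible to `train_frac` of all samples,
#' with at least one subject of each group on each side.
#'
#' @param meta sample metadata (`sample_id`, `subject_id`, `diagnosis`).
#' @param train_frac target fraction of samples in the training set.
#' @param seed RNG seed; the plan is deterministic given the seed.
#' @return list of class `split_plan`: `train`, `test` (sample IDs),
#'   `train_subjects`, `test_subjects`, `train_frac`, `seed`.
#' @export
split_by_subject <- function(meta, train_frac = 0.7, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) stopf("train_frac must be in (0, 1)")
  groups <- unique(meta$diagnosis)
  subj_dx <- meta[!duplicated(meta$subject_id), c("subject_id", "diagnosis")]
  counts <- table(subj_dx$diagnosis)
  if (any(counts < 2)) {
    stopf("each diagnosis group needs >= 2 subjects to split")
  }
  set.seed(seed)
  # random subject order within each group
  ord <- lapply(groups, function(g) {
    s <- subj_dx$subject_id[subj_dx$diagnosis == g]
    sample(s)
  })
  names(ord) <- groups
  samples_per_subject <- table(meta$subject_id)
  target <- train_frac * nrow(meta)

  # choose per-group train counts jointly: minimize |train samples - target|
  best <- NULL
  best_dev <- Inf
  grid <- lapply(groups, function(g) seq_len(length(ord[[g]]) - 1))
  combos <- expand.grid(grid)
  for (i in seq_len(nrow(combos))) {
    train_sub <- unlist(lapply(seq_along(groups), function(j) {
      head(ord[[j]], combos[i, j])
    }))
    n_train <- sum(samples_per_subject[train_sub])
    dev <- abs(n_train - target)
    if (dev < best_dev) {
      best_dev <- dev
      best <- train_sub
    }
  }
  train_subjects <- sort(best)
  test_subjects <- sort(setdiff(subj_dx$subject_id, train_subjects))
  structure(
    list(
      train = meta$sample_id[meta$subject_id %in% train_subjects],
      test = meta$sample_id[meta$subject_id %in% test_subjects],
      train_subjects = train_subjects, test_subjects = test_subjects,
      train_frac = train_frac, seed = as.integer(seed)
    ),
    class = "split_plan"
  )
}

#' Classification metrics for binary predictions
#'
#' Standard accuracy, precision, recall and F1 with a declared positive
#' class. `F1 = 2 * precision * recall / (precision + recall)`, defined as
#' 0 when precision + recall is 0; precision is 0 when nothing is
#' predicted positive, recall is 0 when there are no true positives among
#' predictions (NA-free by convention so panels are always comparable).
#'
#' @param pred predicted labels.
#' @param truth true labels.
#' @param positive label of the positive class (default `"AD"`).
#' @return named list `accuracy, precision, recall, f1`.
#' @export
evaluate_predictions <- function(pred, truth, positive = "AD") {
  if (length(pred) != length(truth)) stopf("pred and truth lengths differ")
  pred <- as.character(pred)
  truth <- as.character(truth)
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  accuracy <- mean(pred == truth)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(accuracy = accuracy, precision = precision, recall = recall, f1 = f1)
}

#' Hoeffding generalization bound
#'
#' Distribution-free error bar on the gap between the observed test error
#' and the out-of-sample error: `eps = sqrt(log(2 / delta) / (2 * n))`;
#' with probability at least `1 - delta` the out-of-sample error is at
#' most `test_error + eps`.
#'
#' @param test_error observed error rate on the held-out test set.
#' @param n_test number of test samples (>= 1).
#' @param delta tolerance in (0, 1).
#' @return list `eps`, `bound` (`= test_error + eps`).
#' @export
hoeffding_bound <- function(test_error, n_test, delta = 0.5) {
  if (n_test < 1) stopf("n_test must be >= 1")
  if (delta <= 0 || delta >= 1) stopf("delta must be in (0, 1)")
  eps <- sqrt(log(2 / delta) / (2 * n_test))
  list(eps = eps, bound = test_error + eps)
}

# regularized quadratic discriminant analysis (Gaussian class-conditionals
# with unequal covariances); regularization keeps small-panel covariances
# invertible.
qda_train <- function(X, y, reg = 1e-3) {
  X <- as.matrix(X)
  classes <- sort(unique(y))
  models <- lapply(classes, function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    S <- cov(Xc)
    if (any(!is.finite(S))) S <- diag(ncol(X))
    S <- S + reg * diag(ncol(X))
    ch <- chol(S)
    list(
      mean = colMeans(Xc),
      chol_inv = backsolve(ch, diag(ncol(X))),
      logdet = 2 * sum(log(diag(ch))),
      logprior = log(nrow(Xc) / nrow(X))
    )
  })
  names(models) <- classes
  structure(list(models = models, classes = classes), class = "hierde_qda")
}

qda_predict <- function(fit, X) {
  X <- as.matrix(X)
  scores <- vapply(fit$models, function(m) {
    D <- sweep(X, 2, m$mean) %*% m$chol_inv
    -0.5 * m$logdet - 0.5 * rowSums(D^2) + m$logprior
  }, numeric(nrow(X)))
  scores <- matrix(scores, nrow = nrow(X))
  fit$classes[max.col(scores, ties.method = "first")]
}

# classifier registry: each entry trains on (X, y) and returns a predictor
classifier_fns <- function(name, opts = list()) {
  switch(name,
    "svm_linear" = function(X, y) {
      m <- e1071::svm(X, factor(y),
        kernel = "linear",
        cost = opts$cost %||% 1, scale = FALSE
      )
      function(Xn) as.character(stats::predict(m, Xn))
    },
    "svm_rbf" = function(X, y) {
      m <- e1071::svm(X, factor(y),
        kernel = "radial",
        cost = opts$cost %||% 1,
        gamma = opts$gamma %||% (1 / (ncol(X) * max(mean(apply(X, 2, var)), 1e-12))),
        scale = FALSE
      )
      function(Xn) as.character(stats::predict(m, Xn))
    },
    "random_forest" = function(X, y) {
      m <- randomForest::randomForest(X, factor(y),
        ntree = opts$ntree %||% 500
      )
      function(Xn) as.character(stats::predict(m, Xn))
    },
    "quadratic_bayes" = function(X, y) {
      m <- qda_train(X, y, reg = opts$reg %||% 1e-3)
      function(Xn) qda_predict(m, Xn)
    },
    stopf("unknown classifier '%s'", name)
  )
}

#' Exhaustive gene-panel search over the top candidate genes
#'
#' For each panel size `N` in `sizes`, evaluates every combination of `N`
#' of the candidate genes by accuracy of the given classifier on the
#' training samples only, selects the best-training-accuracy combination
#' (ties broken by lexicographic gene order: the first combination in
#' enumeration order wins), and only then scores that winning panel once on
#' the held-out test samples. Test data never influences panel selection.
#' Features are standardized with training-set mean and sd only.
#'
#' @param X samples x genes matrix of candidate-gene expression (typically
#'   log2 scale), rownames = sample IDs.
#' @param labels diagnosis per sample (same order as rows of `X`).
#' @param classifier one of `"svm_linear"`, `"svm_rbf"`, `"random_forest"`,
#'   `"quadratic_bayes"`.
#' @param split a `split_plan` from [split_by_subject()].
#' @param sizes panel sizes to search (default `2:10`).
#' @param delta Hoeffding tolerance for the generalization bound.
#' @param positive positive class label.
#' @param opts classifier options (`cost`, `gamma`, `ntree`, `reg`).
#' @param seed seed fixed before each classifier training call, so
#'   stochastic learners (random forest) are reproducible and selection is
#'   independent of evaluation order.
#' @return data.frame with one row per panel size: `classifier, n_panel,
#'   panel` (comma-separated gene IDs), `n_combos, train_acc, test_acc,
#'   precision, recall, f1, hoeffding_eps, out_of_sample_bound`.
#' @export
panel_search <- function(X, labels, classifier, split, sizes = 2:10,
                         delta = 0.5, positive = "AD", opts = list(),
                         seed = 1L) {
  if (is.null(rownames(X))) stopf("X must have sample IDs as rownames")
  if (nrow(X) != length(labels)) stopf("labels must match rows of X")
  genes <- colnames(X)
  if (is.null(genes)) stopf("X must have gene IDs as colnames")
  if (any(sizes < 1) || any(sizes > ncol(X))) {
    stopf("panel sizes must be between 1 and the number of candidate genes")
  }
  itrain <- match(split$train, rownames(X))
  itest <- match(split$test, rownames(X))
  if (anyNA(itrain) || anyNA(itest)) {
    stopf("split sample IDs not all present in X")
  }
  ytrain <- as.character(labels)[itrain]
  ytest <- as.character(labels)[itest]

  # standardize with training statistics only
  mu <- colMeans(X[itrain, , drop = FALSE])
  sdev <- apply(X[itrain, , drop = FALSE], 2, sd)
  sdev[sdev == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  Xtrain <- Xs[itrain, , drop = FALSE]
  Xtest <- Xs[itest, , drop = FALSE]

  make <- classifier_fns(classifier, opts)
  out <- lapply(sizes, function(N) {
    combos <- combn(length(genes), N)
    best_acc <- -Inf
    best_idx <- NULL
    best_predict <- NULL
    for (ci in seq_len(ncol(combos))) {
      cols <- combos[, ci]
      set.seed(seed + ci) # reproducible stochastic learners
      predictor <- tryCatch(
        make(Xtrain[, cols, drop = FALSE], ytrain),
        error = function(e) NULL
      )
      if (is.null(predictor)) next # failed training scores 0
      acc <- mean(predictor(Xtrain[, cols, drop = FALSE]) == ytrain)
      if (acc > best_acc) { # strict: first (lexicographic) combo wins ties
        best_acc <- acc
        best_idx <- cols
        best_predict <- predictor
      }
    }
    if (is.null(best_idx)) stopf("no combination could be trained for N = %d", N)
    pred_test <- best_predict(Xtest[, best_idx, drop = FALSE])
    m <- evaluate_predictions(pred_test, ytest, positive = positive)
    hb <- hoeffding_bound(1 - m$accuracy, length(ytest), delta)
    data.frame(
      classifier = classifier, n_panel = N,
      panel = paste(genes[best_idx], collapse = ","),
      n_combos = ncol(combos), train_acc = best_acc,
      test_acc = m$accuracy, precision = m$precision, recall = m$recall,
      f1 = m$f1, hoeffding_eps = hb$eps,
      out_of_sample_bound = (1 - m$accuracy) + hb$eps,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
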