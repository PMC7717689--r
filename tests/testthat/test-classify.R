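test_that("splits are subject-disjoint, stratified and reproducible", {
  meta <- generate_metadata(cohort_design(), seed = 61)
  sp <- split_by_subject(meta, 0.7, seed = 1)
  expect_length(intersect(sp$train_subjects, sp$test_subjects), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), meta$sample_id)
  # both diagnosis groups represented on both sides
  dx_of <- function(subs) unique(meta$diagnosis[meta$subject_id %in% subs])
  expect_setequal(dx_of(sp$train_subjects), c("AD", "control"))
  expect_setequal(dx_of(sp$test_subjects), c("AD", "control"))
  # train size near the target despite subject granularity
  expect_lt(abs(length(sp$train) - 0.7 * nrow(meta)), 8)
  expect_identical(sp, split_by_subject(meta, 0.7, seed = 1))
  expect_false(identical(sp$train, split_by_subject(meta, 0.7, seed = 2)$train))
})

test_that("binary metrics follow their standard definitions", {
  m <- evaluate_predictions(c("AD", "AD", "control"), c("AD", "AD", "control"))
  expect_equal(unlist(m), c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  # all-negative predictions with true positives: recall 0, f1 0
  m0 <- evaluate_predictions(rep("control", 4), c("AD", "AD", "control", "control"))
  expect_equal(m0$recall, 0)
  expect_equal(m0$f1, 0)
  # mixed case computed by hand: tp=2 fp=1 fn=1 tn=1
  m2 <- evaluate_predictions(
    c("AD", "AD", "AD", "control", "control"),
    c("AD", "AD", "control", "AD", "control")
  )
  expect_equal(m2$precision, 2 / 3)
  expect_equal(m2$recall, 2 / 3)
  expect_equal(m2$accuracy, 3 / 5)
})

test_that("Hoeffding bound matches its closed form and is monotone", {
  hb <- hoeffding_bound(0.17, 51, 0.5)
  expect_equal(hb$eps, sqrt(log(4) / 102), tolerance = 1e-12)
  expect_equal(hb$bound, 0.17 + hb$eps, tolerance = 1e-15)
  eps <- vapply(c(10, 51, 200, 1000), function(n) hoeffding_bound(0, n)$eps, numeric(1))
  expect_true(all(diff(eps) < 0))
  # delta -> 1 lower limit
  expect_equal(hoeffding_bound(0, 100, 1 - 1e-12)$eps, sqrt(log(2) / 200), tolerance = 1e-6)
  expect_error(hoeffding_bound(0.1, 0), "n_test")
  expect_error(hoeffding_bound(0.1, 10, 1.5), "delta")
})

test_that("panel search enumerates C(10, N) combinations and finds a separator", {
  meta <- generate_metadata(cohort_design(), seed = 62)
  set.seed(62)
  n <- nrow(meta)
  X <- matrix(rnorm(n * 10), n, 10,
    dimnames = list(meta$sample_id, paste0("G", 1:10))
  )
  # plant one perfectly separating gene
  X[, "G7"] <- ifelse(meta$diagnosis == "AD", 5, -5) + rnorm(n, 0, 0.1)
  sp <- split_by_subject(meta, 0.7, seed = 3)
  rep_qda <- panel_search(X, meta$diagnosis, "quadratic_bayes", sp, sizes = c(2, 3))
  expect_equal(rep_qda$n_combos, choose(10, c(2, 3)))
  expect_true(all(grepl("G7", rep_qda$panel)))
  expect_true(all(rep_qda$test_acc == 1))
  expect_true(all(rep_qda$f1 == 1))
  # bound column consistency
  expect_equal(
    rep_qda$out_of_sample_bound,
    (1 - rep_qda$test_acc) + rep_qda$hoeffding_eps
  )
})

test_that("every classifier family trains and reports sane metrics", {
  meta <- generate_metadata(cohort_design(), seed = 63)
  set.seed(63)
  n <- nrow(meta)
  X <- matrix(rnorm(n * 4), n, 4,
    dimnames = list(meta$sample_id, paste0("G", 1:4))
  )
  X[, 1] <- X[, 1] + 2 * (meta$diagnosis == "AD")
  sp <- split_by_subject(meta, 0.7, seed = 4)
  for (cf in c("svm_linear", "svm_rbf", "random_forest", "quadratic_bayes")) {
    opts <- if (cf == "random_forest") list(ntree = 100) else list()
    rep1 <- panel_search(X, meta$diagnosis, cf, sp,
      sizes = 2, opts = opts,
      seed = 5
    )
    expect_equal(nrow(rep1), 1)
    expect_true(all(unlist(rep1[, c("train_acc", "test_acc", "precision", "recall", "f1")]) >= 0))
    expect_true(all(unlist(rep1[, c("train_acc", "test_acc", "precision", "recall", "f1")]) <= 1))
    # reproducible given the seed
    rep2 <- panel_search(X, meta$diagnosis, cf, sp, sizes = 2, opts = opts, seed = 5)
    expect_identical(rep1, rep2)
  }
})

test_that("selection is blind to test labels (leakage guard)", {
  meta <- generate_metadata(cohort_design(), seed = 64)
  set.seed(64)
  n <- nrow(meta)
  X <- matrix(rnorm(n * 6), n, 6,
    dimnames = list(meta$sample_id, paste0("G", 1:6))
  )
  X[, 2] <- X[, 2] + 1.5 * (meta$diagnosis == "AD")
  sp <- split_by_subject(meta, 0.7, seed = 6)
  labels <- meta$diagnosis
  shuffled <- labels
  idx <- match(sp$test, meta$sample_id)
  set.seed(1)
  shuffled[idx] <- sample(shuffled[idx])
  a <- panel_search(X, labels, "svm_linear", sp, sizes = 2:3)
  b <- panel_search(X, shuffled, "svm_linear", sp, sizes = 2:3)
  expect_identical(a$panel, b$panel)
  expect_identical(a$train_acc, b$train_acc)
})

test_that("label-permuted data yields chance-level test accuracy", {
  meta <- generate_metadata(cohort_design(), seed = 65)
  n <- nrow(meta)
  majority <- max(table(meta$diagnosis)) / n
  accs <- vapply(1:20, function(s) {
    set.seed(s)
    X <- matrix(rnorm(n * 5), n, 5,
      dimnames = list(meta$sample_id, paste0("G", 1:5))
    )
    # permute diagnosis at the subject level: no real signal
    subj <- unique(meta$subject_id)
    perm <- setNames(sample(meta$diagnosis[match(subj, meta$subject_id)]), subj)
    labels <- perm[meta$subject_id]
    sp <- split_by_subject(meta, 0.7, seed = s)
    r <- panel_search(X, labels, "quadratic_bayes", sp, sizes = 3, seed = s)
    r$test_acc
  }, numeric(1))
  expect_lt(abs(mean(accs) - majority), 0.1)
})
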